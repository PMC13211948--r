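# colliderMR

Index-event (collider) bias correction and Mendelian randomization for
disease prognosis, motivated by the obesity survival paradox in heart
failure: among patients with established disease, higher BMI appears
protective in observational analyses even when its true effect on
prognosis is harmful. Selecting a cohort on disease onset — a collider of
the risk factors that cause onset — induces negative correlations between
those factors; if the alternative factors carry worse prognoses, the
exposure looks protective, and conventional covariate adjustment can make
the distortion worse rather than better.

`colliderMR` provides the complete analysis chain with which this paradox
can be reproduced, diagnosed and corrected end-to-end on synthetic data:

* **Cohort simulator** — Hardy–Weinberg genotypes, a polygenic
  standardized exposure (1 SD = 4.8 BMI units), liability-threshold
  disease onset depending on the exposure, an observed comorbidity and a
  latent severity factor (the collider), and post-onset
  proportional-hazards event times with competing death and
  administrative censoring (~23% events over a 27-month horizon).
* **Survival core** — Cox partial likelihood (Newton–Raphson,
  Efron/Breslow ties, weights, delayed entry; compiled), Fine-Gray
  subdistribution hazards with IPC weights and robust variance,
  restricted cubic splines, BMI categories, scaled Schoenfeld
  diagnostics.
* **Prognosis GWAS** — batched per-variant Cox / logistic / linear scans,
  inverse-variance fixed-effects meta-analysis with Cochran's Q, greedy
  LD pruning (r² < 0.001, 10,000 kb), suggestive hits, power-adjusted
  replication.
* **Bias correction** — raw WLS, Dudbridge and CWLS slopes
  (Hedges–Olkin dilution correction), bivariate CWBLS
  (measurement-error-corrected two-column WLS: the exposure coefficient
  is the bias-corrected causal log-HR per SD, the incidence coefficient
  the bias slope), Slope-Hunter (two-component EM with multi-start), and
  the traditional two-sample MR slope; all return affine-corrected
  summary statistics `beta_prog − b·beta_inc`.
* **Two-sample MR** — allele harmonization (swaps, strand flips,
  palindrome dropping), IVW (multiplicative random-effects), MR-Egger,
  weighted median, weighted mode, HR-per-SD reporting, subgroup
  interaction Z-test, per-variant instrument-validity heterogeneity test.
* **Pipeline** — a seeded, config-driven runner chaining observational
  recapitulation, multi-study GWAS + meta, bias assessment and
  bias-corrected MR into a TSV report bundle with a manifest, plus a thin
  CLI (`inst/cli/collidermr`).

The core MR estimand is the change in log hazard per SD increase in the
exposure, `HR = exp(θ)`; IVW pools per-variant Wald ratios with weights
`bx²/sy²`, and CWBLS solves

```
[ Σw·bx² − Σw·sx²   Σw·bx·bI          ] [θ]   [ Σw·bx·bP ]
[ Σw·bx·bI          Σw·bI² − Σw·seI²  ] [b] = [ Σw·bI·bP ]
```

with `w = 1/seP²`, debiasing the Gram diagonal for the sampling error of
the error-prone regressors.

## Worked example

```r
library(colliderMR)

cfg <- pipeline_config(
  sim = simulation_config(n_individuals = 20000, n_variants = 400),
  n_studies = 3, seed = 5)
run_pipeline(cfg, "demo_run")
cat(readLines("demo_run/summary.txt"), sep = "\n")
```

```
observational: overweight-vs-normal HR 0.935 in cases, 1.312 in population (obs_category_hr.tsv)
observational: case-only exposure HR/SD 0.911 (age+sex), 0.899 (+competitor) (obs_continuous_hr.tsv)
gwas: 1/57 incidence signals replicate in prognosis (52.3 expected) (replication.tsv)
gwas: 0 suggestive prognosis hits at p < 5e-06 (suggestive_hits.tsv)
bias: slopes per method in bias_slopes.tsv (cwbls=-0.346, dudbridge=-0.278, cwls=-0.278, slope_hunter=0.036, mr_slope=-0.285)
mr: instrument valid in cases (0/20 variants flagged at p < 0.0025) (instrument_validity.tsv)
mr: IVW HR/SD 0.967 unadjusted, 1.249 CWBLS-adjusted (mr_results.tsv)
mr: stratum interaction p = 0.665 (mr_interaction.tsv)
```

Reading the output: the true post-onset exposure effect in this simulation
is HR 1.21 per SD. Among cases the overweight category looks *protective*
(HR 0.935) while in the full population it is harmful (HR 1.312) — the
paradox; adjusting the case-only model for the observed comorbidity pushes
the estimate further from the truth (0.911 → 0.899) — the amplification;
incidence hits barely replicate in the prognosis GWAS (1 observed vs 52
expected given power); the bias slopes are negative (selection-induced);
and the naive IVW (0.967) is corrected by CWBLS to 1.249, on the harmful
side of the null and close to the simulated truth. Every number in
`summary.txt` is traceable to a cell in one of the bundle's TSV files.

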