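---
title: "Index-event bias in prognosis genetics: simulation, diagnosis and correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Index-event bias in prognosis genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colliderMR)
```

## The problem

Among patients with established heart failure, observational studies
repeatedly find that higher body-mass index (BMI) is associated with
*lower* mortality — the "obesity survival paradox" — even though obesity is
an established causal risk factor for developing heart failure in the first
place.  A parsimonious explanation is index-event bias, a form of collider
bias: disease onset is caused by several risk factors, so selecting a
cohort on having the disease induces negative correlations between those
factors.  A patient with high BMI needed fewer or less severe alternative
risk factors to develop heart failure; if those alternative factors carry a
worse prognosis, BMI will look protective among cases regardless of its
true effect.

`colliderMR` implements the full analysis chain with which such a paradox
can be reproduced, diagnosed and corrected on synthetic data:

1. a cohort simulator with exactly this collider structure;
2. a survival core (Cox partial likelihood, Fine-Gray subdistribution
   hazards, restricted cubic splines, scaled Schoenfeld diagnostics) for
   the observational recapitulation;
3. per-variant time-to-event GWAS with inverse-variance fixed-effects
   meta-analysis, LD pruning and power-adjusted replication;
4. four index-event-bias corrections for prognosis summary statistics
   (raw/Dudbridge/CWLS slopes, bivariate CWBLS, Slope-Hunter);
5. a two-sample Mendelian-randomization (MR) suite (IVW, MR-Egger,
   weighted median, weighted mode) with allele harmonization, subgroup
   interaction and instrument-validity tests.

## The generative model

Each individual carries independent Hardy–Weinberg dosages $g_{ij} \sim
\mathrm{Bin}(2, f_j)$.  The standardized exposure (BMI analogue) is

$$E_i = \mathrm{std}\Big(\sum_j a_j g_{ij} + \varepsilon_i\Big), \qquad
\varepsilon_i \sim N(0, \sigma_\mathrm{env}^2),$$

displayed on the BMI scale as $27 + 4.8\,E$ kg/m² (one SD of genetically
predicted BMI corresponds to 4.8 kg/m²).  Disease onset follows a logistic
liability,

$$\mathrm{logit}\,P(D_i = 1) = \alpha + \beta_E E_i + \beta_C C_i +
\beta_S S_i + \textstyle\sum_j d_j g_{ij} + \text{age/sex terms},$$

with two exposure-independent risk factors: a recorded comorbidity score
$C_i \sim N(0,1)$ (the `competitor` column) and a *latent* severity factor
$S_i \sim N(0,1)$ that is never emitted in the cohort table.  Direct
liability variants $d_j$ give the onset GWAS genuine signals that are not
mediated by the exposure.  After onset, the primary event time is
exponential with hazard

$$\lambda_i = \lambda_0 \exp\big(\theta E_i + \gamma_C C_i + \gamma_S S_i +
\text{age/sex terms}\big),$$

with an independent exponential competing (non-disease) death time and
administrative censoring.  Constant baseline hazard means proportional
hazards holds exactly and closed-form oracles exist.  Onset-free
individuals are followed for the population-mortality outcome
(`time_pop`/`event_pop`) under the background death hazard alone, so that
the all-individuals analysis of the paradox figure is computable; the
prognosis columns `time`/`event` stay `NA` for them.

### Why the competitor construct is split

If the single strong competitor were fully recorded, adjusting the
case-only Cox model for it would block the only bias path and *recover*
the truth — the well-documented amplification of index-event bias by
covariate adjustment could never appear.  Amplification requires
conditioning on an observed onset cause while correlated severity stays
latent: given onset and the observed comorbidity, exposure and latent
severity must trade off even more sharply.  Hence the defaults give the
recorded competitor a strong onset effect ($\beta_C = 1.5$) but a weak
prognosis effect ($\gamma_C = \log 1.2$), and the latent severity both
strong ($\beta_S = 2$, $\gamma_S = \log 3$).  With these values the
case-only exposure coefficient crosses zero (truth $\theta = \log 1.21$)
and adding the competitor moves it further below the truth.

### Default parameters

| parameter | default | rationale |
|---|---|---|
| exposure SD scale | 4.8 kg/m² | reported SD of genetically predicted BMI |
| true prognosis log-HR per SD | log 1.21 | the causal effect the MR chain must recover |
| exposure heritability | 0.10 over 20 variants | strong but realistic instruments (per-variant F ≈ 250 at n = 50,000); keeps per-variant liability effects moderate so selection bias stays linear in the incidence effect |
| direct-onset effects | 0.25 log-odds/allele over 40 variants | comparable liability magnitude to the exposure instruments and genuinely genome-wide-significant incidence instruments at n = 50,000 — both needed for well-behaved CWBLS |
| onset intercept / $\beta_E$ | −2.5 / 1.5 | onset ≈ 25%, strong exposure selection |
| baseline hazard / censoring | 0.0023 per month / 27 months | ≈ 22–23% primary events over a median ≈ 27-month horizon, matching the motivating cohort |
| competing death hazard | 0.002 per month | modest competing risk; doubles as background population mortality |
| LVEF-like stratum | Bernoulli(0.5) labels on cases | exercise subgroup MR and the interaction Z-test; no true effect difference |

One integer seed drives everything; each simulation stage draws from its
own derived sub-stream, so adding variants does not perturb the survival
draws and identical configurations are bit-identical.

## Survival core: numerical choices

* Newton–Raphson on the partial likelihood with step-halving; convergence
  when max |score| < 1e-8 or the relative log-likelihood change < 1e-10.
  The log-likelihood trace is retained and is non-decreasing.
* Ties: Efron by default (more accurate), Breslow available; identical on
  untied data.  Monotone likelihoods (separation) are flagged, not
  reported as estimates.
* Fine-Gray: expansion of competing failures into (start, stop] rows with
  Kaplan–Meier inverse-probability-of-censoring weights $G(t^-)/G(T_i^-)$,
  fitted with the same weighted partial-likelihood core (Breslow ties, the
  Fine & Gray 1999 convention); robust infinitesimal-jackknife covariance
  grouped by individual, treating the censoring weights as fixed (the
  correction for estimating $G$ is omitted — a documented first-order
  simplification).
* Restricted cubic splines: truncated-power natural-spline basis, knots at
  the 5/25/75/95th percentiles using linear-interpolation quantiles
  (R type 7) — pinned because knot placement is otherwise not reproducible
  across software.  BMI categories compare raw floating-point values to
  the conventional thresholds; 29.95 is overweight, 40 is class III.
* Scaled Schoenfeld residuals use Grambsch–Therneau scaling
  ($\hat\beta + d\,V\hat s_k$) and a Pearson correlation t-test against the
  event-time rank.

## GWAS and meta-analysis

Per-variant Cox scans reuse one compiled driver with a shared risk-set
ordering and warm starts from the covariate-only null model; incidence
scans are per-variant logistic IRLS; exposure scans are closed-form OLS.
Monomorphic variants are emitted with `beta = 0` and `estimable = FALSE`
and excluded downstream.  The fixed-effects meta combines $\ge 2$ studies
with weights $1/\mathrm{se}^2$ and reports Cochran's Q.  LD pruning is
greedy in ascending p-value order (ties broken by chromosome, position),
accepting a variant iff $r^2 < 0.001$ against every accepted variant
within 10,000 kb — the PLINK-style behaviour; the alternative
position-scan ordering is deliberately not implemented.  Power-adjusted
replication counts significant, direction-consistent outcomes (the
direction requirement is a pinned decision; the direction-free count is
also reported) against $\sum_i \Phi(|b_i|/s_i - z_{1-\alpha/2}) +
\Phi(-|b_i|/s_i - z_{1-\alpha/2})$.

## Bias correction

All scalar-slope methods estimate $b$ in $\beta_\mathrm{prog} \approx
\delta - b\,\beta_\mathrm{inc}$ and return the affine-corrected statistics
$\beta_\mathrm{adj} = \beta_\mathrm{prog} - b\,\beta_\mathrm{inc}$ with
first-order propagated errors $\sqrt{\mathrm{se}_P^2 + b^2
\mathrm{se}_I^2}$ (uncertainty in $b$ itself is not propagated — a
documented limitation; whether one should is an open question).

* **raw**: weighted least squares through the origin, weights
  $1/\mathrm{se}_P^2$.
* **CWLS / Dudbridge**: the raw slope times the Hedges–Olkin
  regression-dilution factor $\sum w\beta_I^2 / (\sum w\beta_I^2 - \sum w
  \mathrm{se}_I^2)$.  The two entry points are algebraically identical
  under the defaults and kept separate as distinct sensitivity-analysis
  surfaces.
* **CWBLS** (bivariate): weighted least squares of
  $\beta_\mathrm{prog}$ on the two columns (exposure effect, incidence
  effect), solving measurement-error-corrected normal equations — the
  diagonal of the weighted Gram matrix is debiased by $\sum w\,
  \mathrm{se}^2$ of each regressor.  These estimating equations are the
  package's pinned reading of corrected weighted least squares extended to
  two error-prone regressors.  The exposure coefficient is the
  bias-corrected causal log-HR per SD; the incidence coefficient is the
  bias slope.  The default variant set is the **union** of exposure and
  incidence instruments: with exposure instruments alone the incidence
  column is proportional to the exposure column (instrument effects on
  incidence are exposure-mediated) and the corrected Gram matrix is
  singular by construction.  A genuinely degenerate incidence column
  collapses the model to the univariate corrected regression (= IVW when
  the exposure effects are error-free); a noise-dominated one is rejected.
* **Slope-Hunter**: two-component EM on $(\beta_I, \beta_P)$.  Class 1
  (incidence-only variants) lies on the line up to *sampling* error — its
  conditional variance is pinned to $\mathrm{se}_P^2 + b^2\mathrm{se}_I^2$
  rather than estimated, because with a free variance the free-covariance
  class 2 can mimic the line exactly and the labels are unidentifiable.
  Class 2's conditional variance is floored at the same sampling level
  (direct effects only add variance).  Initialization: k-means for start
  1, a dominant-class-1 start, random responsibilities for the rest;
  near-tied likelihoods resolve toward the larger class-1 mass, and BIC
  model selection against the one-component all-incidence-only model
  handles pure-line data, where the two-component labels are inherently
  flat in the likelihood.  Per-start slopes are returned: the method's
  sensitivity to inputs is a reportable output, not a hidden failure.
* **mr_slope**: the traditional two-sample MR slope of prognosis on
  incidence using incidence-significant instruments.

Two structural facts, visible in the package's own simulations, are worth
knowing.  First, one-sample overlap between the exposure/incidence and
prognosis statistics correlates their sampling errors and biases CWBLS,
whose Gram correction assumes independent errors; the acceptance analyses
therefore use a two-sample layout with independent cohorts per trait, as
in the motivating study design.  Second, when exposure instruments sit in
a scalar-slope estimation set, the causal pathway $\theta$ leaks into the
slope (the estimator regresses $\theta a - b\,\beta_I$ on $\beta_I \propto
a$), so Dudbridge/CWLS corrections over-correct the exposure instruments;
CWBLS separates the two columns and is the primary correction, mirroring
the analysis choice of the motivating study.

## MR estimators

* **IVW**: $\hat\theta = \sum b_x b_y / s_y^2 \big/ \sum b_x^2/s_y^2$;
  multiplicative random-effects SE (fixed-effect SE inflated by
  $\max(1, \sqrt{Q/(m-1)})$) by default, fixed-effect behind a flag — the
  mainstream convention when the underlying software choice is unknown.
* **MR-Egger**: weighted regression with intercept after orienting
  exposure effects positive; intercept = directional-pleiotropy test;
  same SE inflation convention (floored at 1).
* **Weighted median**: inverse-variance weights on the Wald ratios,
  linear interpolation between bracketing order statistics at cumulative
  weight 0.5 (pinned and unit-tested); seeded parametric bootstrap SE.
* **Weighted mode**: normal-kernel density over the ratios with
  inverse-variance weights, modified Silverman bandwidth
  $0.9\min(\mathrm{sd},\mathrm{mad})\,m^{-1/5}$ times a user factor;
  seeded bootstrap SE.
* Harmonization matches by id, flips swapped alleles, resolves strand
  flips by complement, and drops palindromic variants with exposure EAF in
  0.42–0.58 (conservative; strand inference is deliberately not
  attempted).  Every action is recorded per variant.
* Instrument thresholds default to $5\times10^{-8}$, suggestive hits to
  $5\times10^{-6}$, pruning to $r^2<0.001$ in 10,000 kb, Bonferroni base
  0.05.

## What the tests do and do not show

The acceptance suite runs, at documented scales chosen for single-CPU
desk-top runtimes:

* paradox reproduction and adjustment amplification on three cohorts of
  200,000 individuals;
* causal-effect recovery (relative bias of the CWBLS-corrected IVW and
  its CI coverage against $\log 1.21$) over 200 two-sample replicates of
  50,000 individuals and 2,000 variants (20 exposure-causal), with the
  auxiliary exposure/incidence cohorts simulating the 60-variant causal
  block — null variants carry no information for the slope methods after
  dilution correction, while the prognosis GWAS scans all 2,000 variants;
* oracle equivalences (grid-search Cox, hand meta-analysis, all-pairs LD
  pruning, normal-equations slopes, cumulative-weight-scan median);
* null calibration (bias slopes under selection independent of the
  exposure; IVW type-I error over 500 null replicates).

The simulator emulates the causal structure of the motivating study, not
its data realism: variants are independent (no LD; pruning correctness is
tested on purpose-built correlated fixtures), effects are homogeneous
within class, hazards are constant in time, all cases are incident with
t = 0 at onset (no prevalent-case left truncation), and censoring is
administrative.  Passing tests demonstrate that the estimators do what
their theory promises under their assumptions — not that any particular
real dataset satisfies those assumptions.

## Known limitations

* Adjusted-statistics SEs ignore the uncertainty in the bias slope.
* The Fine-Gray robust variance conditions on the estimated censoring
  distribution.
* Hazard-ratio non-collapsibility means even a perfectly corrected
  per-variant scan targets a slightly attenuated *marginal* effect: under
  the default severity frailty the shrink is several percent (a dedicated
  no-selection test measures it), and together with second-order
  finite-instrument effects the corrected estimate sits close to the 10%
  relative-bias band of the recovery check against the conditional truth.
  Comparisons against conditional effects should keep this estimand gap in
  mind; it is a property of the hazard-ratio scale, not of the bias
  correction.
* Nonlinear MR is out of scope by design.
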