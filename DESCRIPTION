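Package: colliderMR
Title: Index-Event Bias Correction and Mendelian Randomization for
    Disease Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, diagnosis and correction of index-event
    (collider) bias in genetic studies of disease prognosis, motivated by
    the obesity survival paradox in heart failure.  Provides a cohort
    simulator with liability-threshold disease onset and
    proportional-hazards prognosis, a survival-analysis core (Cox partial
    likelihood with Efron/Breslow ties, Fine-Gray subdistribution
    hazards, restricted cubic splines, scaled Schoenfeld diagnostics),
    per-variant time-to-event GWAS with inverse-variance fixed-effects
    meta-analysis and LD pruning, four index-event-bias correction
    estimators (Dudbridge, CWLS, bivariate CWBLS, Slope-Hunter), and a
    two-sample Mendelian-randomization suite (IVW, MR-Egger, weighted
    median, weighted mode) with allele harmonization, subgroup
    interaction tests and instrument-validity heterogeneity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cmprsk,
    jsonlite,
    metafor,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
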