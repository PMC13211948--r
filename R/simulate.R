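# Synthetic cohorts with the causal structure that generates the obesity
# survival paradox: a polygenic exposure and an independent competing risk
# factor both raise the probability of disease onset (the collider), and both
# carry proportional-hazards effects on post-onset prognosis.

# fixed covariate effects (age per year from 66, male sex), chosen to make
# covariate adjustment in the GWAS non-trivial without dominating the model
.AGE_ONSET <- 0.02
.SEX_ONSET <- 0.30
.AGE_PROG <- 0.02
.SEX_PROG <- 0.20

#' Simulation configuration for a prognosis-cohort study
#'
#' Collects the free parameters of the cohort simulator.  The defaults encode
#' the study conditions the package is designed around: a standardized
#' polygenic exposure on the BMI scale (1 SD = 4.8 kg/m2), a non-genetic
#' competing risk factor, liability-threshold disease onset depending on both
#' (the collider), an exposure effect on post-onset hazard of log(1.21) per
#' SD with a much stronger competitor effect, and administrative censoring at
#' 27 months giving roughly a 23% primary event rate.
#'
#' When `variant_effects` is `NULL`, the first `n_exposure_causal` variants
#' receive equal-variance exposure effects totalling `exposure_h2` of the
#' exposure variance, and the following `n_onset_causal` variants receive
#' direct liability effects (`onset_variant_effects`) of 0.25 log-odds per
#' allele.  Direct-onset variants have no pathway to prognosis, so they act
#' as incidence-only instruments for the bias-correction estimators.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of independent variants.
#' @param maf vector of effect-allele frequencies in (0, 0.5]; recycled to
#'   `n_variants`.  Default: deterministic draws in (0.05, 0.5) under the
#'   config seed.
#' @param variant_effects per-allele effects on the (pre-standardization)
#'   exposure; default as described above.
#' @param onset_variant_effects per-allele direct log-odds effects on the
#'   onset liability; default as described above.
#' @param n_exposure_causal,n_onset_causal,exposure_h2 used only to build the
#'   default effect vectors.
#' @param exposure_env_sd SD of the non-genetic exposure component; default
#'   `sqrt(1 - exposure_h2)` so the pre-standardization exposure has variance
#'   close to 1.
#' @param exposure_scale_sd units per SD of exposure on the measurement scale
#'   (BMI: 4.8 kg/m2).
#' @param exposure_scale_mean measurement-scale location (kg/m2).
#' @param onset_intercept,onset_beta_exposure,onset_beta_competitor,onset_beta_severity
#'   logistic liability coefficients for disease onset.  `competitor` is the
#'   recorded comorbidity column; `severity` is a latent standard-normal
#'   factor never emitted in the cohort table.
#' @param prognosis_loghr_exposure,prognosis_loghr_competitor,prognosis_loghr_severity
#'   true per-SD log hazard ratios on the post-onset primary event.  The
#'   defaults give the latent severity factor a strong effect (log 3) and
#'   the observed competitor a weak one (log 1.2), so conditioning on onset
#'   biases the case-only exposure association downward and additionally
#'   adjusting for the observed competitor amplifies the bias instead of
#'   removing it.
#' @param baseline_hazard_rate primary events per month at covariate zero.
#' @param competing_death_rate hazard of competing (non-disease) death, also
#'   used as the background mortality of onset-free individuals.
#' @param censor_time administrative censoring horizon, months.
#' @param stratum_prob probability that a case is labelled `"reduced"` (vs
#'   `"preserved"`, an LVEF-like stratum); `NULL` for no strata.
#' @param age_beta_onset,sex_beta_onset,age_loghr,sex_loghr covariate
#'   effects (age per year from 66, male sex) on the onset liability and
#'   the post-onset log hazard.
#' @param seed integer RNG seed; all stages derive independent sub-seeds.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 10000L,
                              n_variants = 200L,
                              maf = NULL,
                              variant_effects = NULL,
                              onset_variant_effects = NULL,
                              n_exposure_causal = 20L,
                              n_onset_causal = 40L,
                              exposure_h2 = 0.1,
                              exposure_env_sd = NULL,
                              exposure_scale_sd = 4.8,
                              exposure_scale_mean = 27,
                              onset_intercept = -2.5,
                              onset_beta_exposure = 1.5,
                              onset_beta_competitor = 1.5,
                              onset_beta_severity = 2.0,
                              prognosis_loghr_exposure = log(1.21),
                              prognosis_loghr_competitor = log(1.2),
                              prognosis_loghr_severity = log(3),
                              baseline_hazard_rate = 0.0023,
                              competing_death_rate = 0.002,
                              censor_time = 27,
                              stratum_prob = 0.5,
                              age_beta_onset = .AGE_ONSET,
                              sex_beta_onset = .SEX_ONSET,
                              age_loghr = .AGE_PROG,
                              sex_loghr = .SEX_PROG,
                              seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (n_variants < 0) stop("n_variants must be >= 0")
  if (is.null(maf)) {
    maf <- if (n_variants > 0)
      with_seed(stage_seed(seed, 90L), runif(n_variants, 0.05, 0.5))
    else numeric(0)
  }
  maf <- rep_len(maf, n_variants)
  check_maf(maf)
  if (is.null(variant_effects)) {
    variant_effects <- numeric(n_variants)
    idx <- seq_len(min(n_exposure_causal, n_variants))
    variant_effects[idx] <-
      sqrt((exposure_h2 / max(length(idx), 1)) /
             (2 * maf[idx] * (1 - maf[idx])))
  }
  variant_effects <- rep_len(variant_effects, n_variants)
  if (is.null(onset_variant_effects)) {
    onset_variant_effects <- numeric(n_variants)
    idx <- seq_len(min(n_onset_causal, max(n_variants - n_exposure_causal, 0))) +
      n_exposure_causal
    onset_variant_effects[idx] <- 0.25
  }
  onset_variant_effects <- rep_len(onset_variant_effects, n_variants)
  if (is.null(exposure_env_sd)) exposure_env_sd <- sqrt(1 - exposure_h2)
  rates <- c(baseline_hazard_rate = baseline_hazard_rate,
             competing_death_rate = competing_death_rate)
  if (any(rates < 0)) stop("hazard rates must be >= 0")
  if (censor_time <= 0) stop("censor_time must be > 0")
  coefs <- c(onset_intercept, onset_beta_exposure, onset_beta_competitor,
             onset_beta_severity, prognosis_loghr_exposure,
             prognosis_loghr_competitor, prognosis_loghr_severity)
  if (any(!is.finite(coefs))) stop("model coefficients must be finite")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    maf = maf,
    variant_effects = variant_effects,
    onset_variant_effects = onset_variant_effects,
    exposure_env_sd = exposure_env_sd,
    exposure_scale_sd = exposure_scale_sd,
    exposure_scale_mean = exposure_scale_mean,
    onset_intercept = onset_intercept,
    onset_beta_exposure = onset_beta_exposure,
    onset_beta_competitor = onset_beta_competitor,
    onset_beta_severity = onset_beta_severity,
    prognosis_loghr_exposure = prognosis_loghr_exposure,
    prognosis_loghr_competitor = prognosis_loghr_competitor,
    prognosis_loghr_severity = prognosis_loghr_severity,
    baseline_hazard_rate = baseline_hazard_rate,
    competing_death_rate = competing_death_rate,
    censor_time = censor_time,
    stratum_prob = stratum_prob,
    age_beta_onset = age_beta_onset,
    sex_beta_onset = sex_beta_onset,
    age_loghr = age_loghr,
    sex_loghr = sex_loghr,
    seed = as.integer(seed)), class = "simulation_config")
}

check_maf <- function(maf) {
  bad <- which(!is.finite(maf) | maf <= 0 | maf > 0.5)
  if (length(bad) > 0)
    stop(sprintf("maf must lie in (0, 0.5]; offending index: %s",
                 paste(head(bad, 5), collapse = ", ")))
  invisible(maf)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  individuals: %d, variants: %d (%d exposure-causal, %d onset-causal)\n",
              x$n_individuals, x$n_variants,
              sum(x$variant_effects != 0), sum(x$onset_variant_effects != 0)))
  cat(sprintf("  onset: logit = %.2f + %.2f E + %.2f C + %.2f S (+ direct variants)\n",
              x$onset_intercept, x$onset_beta_exposure,
              x$onset_beta_competitor, x$onset_beta_severity))
  cat(sprintf("  prognosis: logHR %.3f/SD exposure, %.3f/SD competitor, %.3f/SD severity; baseline %.4g/mo, censor %.4g mo\n",
              x$prognosis_loghr_exposure, x$prognosis_loghr_competitor,
              x$prognosis_loghr_severity,
              x$baseline_hazard_rate, x$censor_time))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each column j is drawn Binomial(2, `maf[j]`) independently across
#' individuals and variants.
#'
#' @param n_individuals number of rows.
#' @param maf vector of allele frequencies in (0, 0.5].
#' @param seed integer seed.
#' @return integer matrix of dosages in \{0, 1, 2\}, columns named `v1..vM`.
#' @export
simulate_genotypes <- function(n_individuals, maf, seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  check_maf(maf)
  g <- with_seed(seed, sim_genotypes_cpp(as.integer(n_individuals), maf))
  colnames(g) <- paste0("v", seq_along(maf))
  g
}

#' Simulate a standardized polygenic exposure
#'
#' Exposure = centred genetic score + Normal(0, `env_sd`) noise, then
#' standardized to mean 0, SD 1 in the generated sample.  The realized
#' per-allele effects on the standardized exposure are recorded in attribute
#' `effects_std` for truth-tracking.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param variant_effects per-allele effects, one per column of `genotypes`.
#' @param env_sd SD of the non-genetic component.
#' @param seed integer seed.
#' @return standardized numeric vector with attributes `effects_std`,
#'   `sd_raw` and `mean_raw`.
#' @export
simulate_exposure <- function(genotypes, variant_effects, env_sd, seed = 1L) {
  if (length(variant_effects) != ncol(genotypes))
    stop("variant_effects length must equal the number of genotype columns")
  if (env_sd < 0) stop("env_sd must be >= 0")
  score <- genetic_score_cpp(genotypes, as.numeric(variant_effects))
  score <- score - mean(score)
  noise <- with_seed(seed, rnorm(nrow(genotypes), 0, env_sd))
  raw <- score + noise
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop("degenerate exposure: no genetic or environmental variance")
  out <- (raw - mean(raw)) / s
  attr(out, "effects_std") <- as.numeric(variant_effects) / s
  attr(out, "sd_raw") <- s
  attr(out, "mean_raw") <- mean(raw)
  out
}

#' Simulate disease onset (the collider)
#'
#' P(onset) = logistic(intercept + bE * exposure + bU * competitor + offset).
#' The competitor must be generated independently of the exposure before
#' selection; conditioning on `onset = 1` then induces the negative
#' exposure-competitor correlation that drives index-event bias.
#'
#' @param exposure,competitor standardized vectors of equal length.
#' @param intercept,beta_exposure,beta_competitor liability coefficients.
#' @param seed integer seed.
#' @param offset optional additional liability (direct variant effects,
#'   covariates).
#' @return integer 0/1 vector.
#' @export
simulate_onset <- function(exposure, competitor, intercept, beta_exposure,
                           beta_competitor, seed = 1L, offset = 0) {
  if (length(exposure) != length(competitor))
    stop("exposure and competitor must have equal length")
  if (any(!is.finite(c(intercept, beta_exposure, beta_competitor))))
    stop("onset coefficients must be finite")
  lin <- intercept + beta_exposure * exposure + beta_competitor * competitor +
    offset
  pr <- stats::plogis(lin)
  with_seed(seed, rbinom(length(pr), 1L, pr))
}

#' Simulate post-onset prognosis
#'
#' Given the case subset, draws a primary event time with hazard
#' `baseline_hazard_rate * exp(bE' * exposure + bU' * competitor + offset)`
#' (constant baseline hazard, so proportional hazards holds exactly), an
#' independent competing death time with hazard `competing_death_rate`, and
#' applies administrative censoring at `censor_time`.
#'
#' @param exposure,competitor values for the onset cases.
#' @param loghr_exposure,loghr_competitor per-SD log hazard ratios.
#' @param baseline_hazard_rate,competing_death_rate,censor_time event-time
#'   law parameters (rates per month, horizon in months).
#' @param seed integer seed.
#' @param offset optional additional log-hazard (covariates).
#' @return data frame with `time` (> 0) and `event` (factor: primary,
#'   competing, censored).
#' @export
simulate_prognosis <- function(exposure, competitor, loghr_exposure,
                               loghr_competitor, baseline_hazard_rate,
                               competing_death_rate, censor_time,
                               seed = 1L, offset = 0) {
  n <- length(exposure)
  if (n == 0) stop("empty case set")
  if (baseline_hazard_rate <= 0 && competing_death_rate <= 0 &&
      !is.finite(censor_time))
    stop("no events possible: zero hazards with infinite censoring")
  if (censor_time <= 0) stop("censor_time must be > 0")
  haz <- baseline_hazard_rate *
    exp(loghr_exposure * exposure + loghr_competitor * competitor + offset)
  with_seed(seed, {
    t1 <- if (baseline_hazard_rate > 0) rexp(n, haz) else rep(Inf, n)
    t2 <- if (competing_death_rate > 0) rexp(n, competing_death_rate)
          else rep(Inf, n)
    time <- pmin(t1, t2, censor_time)
    event <- ifelse(t1 <= time & t1 <= t2, "primary",
                    ifelse(t2 <= time, "competing", "censored"))
    data.frame(time = time,
               event = factor(event,
                              levels = c("primary", "competing", "censored")))
  })
}

make_variant_info <- function(maf) {
  m <- length(maf)
  chrom <- rep(1:22, length.out = m)
  pos <- integer(m)
  for (cc in unique(chrom)) {
    k <- which(chrom == cc)
    # spacing > the 10 Mb pruning window so independent variants are never
    # compared against each other by position-windowed LD pruning
    pos[k] <- seq_along(k) * 11000000L
  }
  data.frame(variant_id = paste0("v", seq_len(m)), chrom = chrom, pos = pos,
             effect_allele = "A", other_allele = "G", maf = maf,
             stringsAsFactors = FALSE)
}

#' Simulate a full prognosis-cohort study
#'
#' Runs every stage of the generative model under per-stage sub-seeds:
#' genotypes, covariates (age, sex), exposure, an independent standard-normal
#' competitor, liability-threshold onset, post-onset prognosis for cases, a
#' population mortality outcome defined for everyone (cases follow the
#' prognosis process; onset-free individuals are exposed to the background
#' death hazard `competing_death_rate`), and optional LVEF-like stratum
#' labels for cases.
#'
#' @param config a [simulation_config()].
#' @return a `cohort_table`: a data frame with one row per individual
#'   (columns `id`, `age`, `sex`, `exposure`, `exposure_raw`, `competitor`,
#'   `onset`, `time`, `event`, `stratum`, `time_pop`, `event_pop`; prognosis
#'   `time`/`event` are `NA` for onset-free individuals) and attributes
#'   `genotypes` (dosage matrix), `variants` (annotation), `effects_std`
#'   (true per-allele effects on the standardized exposure) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals
  seed <- config$seed
  g <- if (config$n_variants > 0)
    simulate_genotypes(n, config$maf, stage_seed(seed, 1L))
  else matrix(integer(0), nrow = n, ncol = 0)
  cov <- with_seed(stage_seed(seed, 2L), {
    data.frame(age = rnorm(n, 66, 9.5), sex = rbinom(n, 1L, 0.68))
  })
  exposure <- if (config$n_variants > 0 || config$exposure_env_sd > 0) {
    simulate_exposure(g, config$variant_effects, config$exposure_env_sd,
                      stage_seed(seed, 3L))
  } else stop("degenerate exposure: no genetic or environmental variance")
  competitor <- with_seed(stage_seed(seed, 4L), rnorm(n))
  severity <- with_seed(stage_seed(seed, 9L), rnorm(n))
  direct <- if (config$n_variants > 0) {
    d <- genetic_score_cpp(g, config$onset_variant_effects)
    d - mean(d)
  } else 0
  onset_offset <- direct + config$onset_beta_severity * severity +
    config$age_beta_onset * (cov$age - 66) + config$sex_beta_onset * cov$sex
  onset <- simulate_onset(exposure, competitor, config$onset_intercept,
                          config$onset_beta_exposure,
                          config$onset_beta_competitor,
                          stage_seed(seed, 5L), offset = onset_offset)
  cases <- which(onset == 1L)
  time <- rep(NA_real_, n)
  event <- factor(rep(NA_character_, n),
                  levels = c("primary", "competing", "censored"))
  if (length(cases) > 0) {
    prog_offset <- config$prognosis_loghr_severity * severity[cases] +
      config$age_loghr * (cov$age[cases] - 66) +
      config$sex_loghr * cov$sex[cases]
    prog <- simulate_prognosis(exposure[cases], competitor[cases],
                               config$prognosis_loghr_exposure,
                               config$prognosis_loghr_competitor,
                               config$baseline_hazard_rate,
                               config$competing_death_rate,
                               config$censor_time,
                               stage_seed(seed, 6L), offset = prog_offset)
    time[cases] <- prog$time
    event[cases] <- prog$event
  }
  # population mortality: everyone is followed; onset-free individuals face
  # only the background death hazard
  time_pop <- rep(config$censor_time, n)
  event_pop <- rep(0L, n)
  noncases <- setdiff(seq_len(n), cases)
  if (length(noncases) > 0 && config$competing_death_rate > 0) {
    tbg <- with_seed(stage_seed(seed, 7L),
                     rexp(length(noncases), config$competing_death_rate))
    died <- tbg < config$censor_time
    time_pop[noncases] <- pmin(tbg, config$censor_time)
    event_pop[noncases] <- as.integer(died)
  }
  if (length(cases) > 0) {
    time_pop[cases] <- time[cases]
    event_pop[cases] <- as.integer(event[cases] != "censored")
  }
  stratum <- rep(NA_character_, n)
  if (!is.null(config$stratum_prob) && length(cases) > 0) {
    stratum[cases] <- with_seed(stage_seed(seed, 8L),
                                ifelse(runif(length(cases)) <
                                         config$stratum_prob,
                                       "reduced", "preserved"))
  }
  out <- data.frame(id = seq_len(n), age = cov$age, sex = cov$sex,
                    exposure = as.numeric(exposure),
                    exposure_raw = as.numeric(exposure) *
                      config$exposure_scale_sd + config$exposure_scale_mean,
                    competitor = competitor, onset = onset, time = time,
                    event = event, stratum = stratum, time_pop = time_pop,
                    event_pop = event_pop, stringsAsFactors = FALSE)
  attr(out, "genotypes") <- g
  attr(out, "variants") <- make_variant_info(config$maf)
  attr(out, "effects_std") <- attr(exposure, "effects_std") %||%
    numeric(config$n_variants)
  attr(out, "config") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Per-variant summary statistics from a simulated cohort
#'
#' * `incidence`: logistic regression of onset on dosage plus covariates,
#'   over all individuals (log-odds scale).
#' * `prognosis`: per-variant Cox regression of the primary event among
#'   onset cases (log-hazard scale), competing deaths censored.
#' * `exposure`: per-variant linear regression of the standardized exposure
#'   (per-SD scale).
#'
#' Monomorphic variants are emitted with `beta = 0` and `estimable = FALSE`
#' and are excluded by downstream stages.
#'
#' @param cohort a `cohort_table`.
#' @param which which association scan to run.
#' @param covariates column names of `cohort` to adjust for (incidence and
#'   prognosis scans).
#' @param ties tie handling for the prognosis scan.
#' @return a `summary_stats` data frame in the package TSV dialect
#'   (`variant_id chrom pos effect_allele other_allele eaf beta se pvalue n`
#'   plus `estimable`).
#' @export
build_summary_stats <- function(cohort,
                                which = c("incidence", "prognosis",
                                          "exposure"),
                                covariates = c("age", "sex"),
                                ties = c("efron", "breslow")) {
  stopifnot(inherits(cohort, "cohort_table"))
  which <- match.arg(which)
  ties <- match.arg(ties)
  g <- attr(cohort, "genotypes")
  vi <- attr(cohort, "variants")
  if (is.null(g) || ncol(g) == 0) stop("cohort carries no genotypes")
  cm <- if (length(covariates) > 0)
    as_covariate_matrix(cohort[, covariates, drop = FALSE], nrow(cohort))
  else NULL
  if (which == "incidence") {
    res <- logistic_gwas_cpp(as.integer(cohort$onset), g, cm, 25L, 1e-8)
    n_used <- nrow(cohort)
  } else if (which == "prognosis") {
    cases <- which(cohort$onset == 1L)
    if (length(cases) == 0) stop("empty case set")
    res <- cox_gwas_cpp(cohort$time[cases],
                        as.integer(cohort$event[cases] == "primary"),
                        g[cases, , drop = FALSE],
                        if (is.null(cm)) NULL else cm[cases, , drop = FALSE],
                        ties == "efron", 25L, 1e-8, 1e-10)
    n_used <- length(cases)
  } else {
    res <- linear_gwas_cpp(as.numeric(cohort$exposure), g)
    n_used <- nrow(cohort)
  }
  out <- data.frame(vi[, c("variant_id", "chrom", "pos", "effect_allele",
                           "other_allele")],
                    eaf = colMeans(g) / 2,
                    beta = res[, "beta"], se = res[, "se"],
                    pvalue = wald_p(res[, "beta"], res[, "se"]),
                    n = n_used,
                    estimable = res[, "estimable"] == 1 &
                      res[, "converged"] == 1,
                    stringsAsFactors = FALSE)
  out$beta[!out$estimable] <- 0
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read a cohort table as tab-delimited text
#'
#' Genotype dosages are stored as columns `g1..gM` after the phenotype
#' columns.  `read_cohort()` reconstructs the dosage matrix and the default
#' variant annotation; the generating configuration is not round-tripped.
#'
#' @param cohort a `cohort_table`.
#' @param path file path (a `.gz` suffix compresses).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  g <- attr(cohort, "genotypes")
  df <- as.data.frame(cohort)
  if (!is.null(g) && ncol(g) > 0) {
    gd <- as.data.frame(g)
    names(gd) <- paste0("g", seq_len(ncol(g)))
    df <- cbind(df, gd)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gcols <- grep("^g[0-9]+$", names(df))
  g <- as.matrix(df[, gcols, drop = FALSE])
  storage.mode(g) <- "integer"
  colnames(g) <- paste0("v", seq_len(ncol(g)))
  df <- df[, setdiff(seq_along(df), gcols), drop = FALSE]
  df$event <- factor(df$event, levels = c("primary", "competing", "censored"))
  attr(df, "genotypes") <- g
  attr(df, "variants") <- make_variant_info(colMeans(g) / 2)
  class(df) <- c("cohort_table", "data.frame")
  df
}
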