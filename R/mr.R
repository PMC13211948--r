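# Two-sample Mendelian randomization: instrument selection, allele
# harmonization, IVW / MR-Egger / weighted median / weighted mode, scale
# conversion, subgroup interaction and instrument-validity tests.

#' Construct an MR estimate record
#'
#' Container used by every estimator: the effect on the log-hazard-per-SD
#' scale with its Wald CI and p-value, the instrument count, optional
#' heterogeneity statistics and the SD-to-unit conversion (default 4.8
#' exposure units per SD).
#'
#' @param method method tag (e.g. `"ivw"`, `"egger_slope"`).
#' @param beta,se estimate and standard error on the log scale.
#' @param n_variants number of instruments used.
#' @param q,q_df optional heterogeneity statistic and degrees of freedom.
#' @param sd_units measurement units per SD of exposure.
#' @param extra free-form provenance (seeds, bandwidths).
#' @return an object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_variants, q = NA_real_,
                        q_df = NA_integer_, sd_units = 4.8,
                        extra = NULL) {
  z <- z975()
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 p = wald_p(beta, se), n_variants = n_variants,
                 q = q, q_df = q_df,
                 q_p = if (is.finite(q) && !is.na(q_df) && q_df > 0)
                   pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
                 sd_units = sd_units, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: %d variants\n", x$method, x$n_variants))
  cat(sprintf("  beta %.4f (se %.4f) per SD (%.1f units); HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$beta, x$se, x$sd_units, exp(x$beta), exp(x$ci_low),
              exp(x$ci_high), x$p))
  if (is.finite(x$q) && !is.na(x$q_df))
    cat(sprintf("  heterogeneity Q = %.2f on %d df (p = %.3g)\n",
                x$q, x$q_df, x$q_p))
  invisible(x)
}

#' Select exposure instruments
#'
#' Genome-wide-significant exposure variants, optionally LD-pruned against a
#' reference dosage panel.
#'
#' @param exposure `summary_stats` table.
#' @param p_threshold significance threshold (default 5e-8).
#' @param ref_genotypes optional reference dosages for [ld_prune()].
#' @param r2_max,window_kb pruning parameters.
#' @return the selected rows of `exposure`.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8,
                               ref_genotypes = NULL, r2_max = 0.001,
                               window_kb = 10000) {
  sel <- exposure[(exposure$estimable %||% TRUE) &
                    exposure$pvalue < p_threshold, , drop = FALSE]
  if (!is.null(ref_genotypes) && nrow(sel) > 0)
    sel <- ld_prune(sel, ref_genotypes, r2_max, window_kb)
  sel
}

allele_complement <- function(a) chartr("ACGT", "TGCA", a)

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by id and aligns the outcome effect to the exposure
#' effect allele: direct matches are kept, swapped allele pairs flip the
#' outcome beta (and frequency), strand flips are resolved by complementing
#' the outcome alleles, palindromic (A/T, C/G) variants with exposure
#' frequency inside the ambiguity window are dropped, and irreconcilable
#' allele pairs are dropped with a warning.  Every action is recorded.
#'
#' @param exposure,outcome `summary_stats` tables with allele and `eaf`
#'   columns.
#' @param palindrome_eaf_window frequency window in which palindromic
#'   variants are ambiguous (default 0.42-0.58).
#' @param p_threshold exposure significance filter applied before matching
#'   (`NULL` to disable).
#' @return class `instrument_set`: data frame `variant_id`, `bx`, `sx`,
#'   `by`, `sy`, `eaf`, `action`; rows with `action` `"kept"`/`"flipped"`
#'   form the analysis set used by the estimators.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_eaf_window = c(0.42, 0.58),
                      p_threshold = 5e-8) {
  if (!is.null(p_threshold))
    exposure <- exposure[(exposure$estimable %||% TRUE) &
                           exposure$pvalue < p_threshold, , drop = FALSE]
  if (nrow(exposure) == 0) stop("no exposure instruments at the threshold")
  if (any(duplicated(exposure$variant_id)))
    stop("duplicate variant ids in exposure table")
  m <- match(exposure$variant_id, outcome$variant_id)
  n <- nrow(exposure)
  by <- sy <- rep(NA_real_, n)
  action <- rep("dropped_missing", n)
  ea_x <- toupper(exposure$effect_allele)
  oa_x <- toupper(exposure$other_allele)
  palindromic <- ea_x == allele_complement(oa_x)
  ambiguous <- palindromic & exposure$eaf >= palindrome_eaf_window[1] &
    exposure$eaf <= palindrome_eaf_window[2]
  out_est <- outcome$estimable %||% rep(TRUE, nrow(outcome))
  out_ok <- out_est & is.finite(outcome$beta) & is.finite(outcome$se) &
    outcome$se > 0
  for (i in seq_len(n)) {
    j <- m[i]
    if (is.na(j) || !out_ok[j]) next
    if (ambiguous[i]) { action[i] <- "dropped_palindromic"; next }
    ea_y <- toupper(outcome$effect_allele[j])
    oa_y <- toupper(outcome$other_allele[j])
    aligned <- NA
    if (ea_y == ea_x[i] && oa_y == oa_x[i]) aligned <- FALSE
    else if (ea_y == oa_x[i] && oa_y == ea_x[i]) aligned <- TRUE
    else {
      ea_yc <- allele_complement(ea_y)
      oa_yc <- allele_complement(oa_y)
      if (ea_yc == ea_x[i] && oa_yc == oa_x[i]) aligned <- FALSE
      else if (ea_yc == oa_x[i] && oa_yc == ea_x[i]) aligned <- TRUE
    }
    if (is.na(aligned)) next
    by[i] <- if (aligned) -outcome$beta[j] else outcome$beta[j]
    sy[i] <- outcome$se[j]
    action[i] <- if (aligned) "flipped" else "kept"
  }
  bad <- action == "dropped_missing"
  if (any(bad))
    warning(sprintf("%d variant(s) dropped (missing or irreconcilable alleles): %s",
                    sum(bad),
                    paste(head(exposure$variant_id[bad], 5), collapse = ", ")))
  out <- data.frame(variant_id = exposure$variant_id,
                    bx = exposure$beta, sx = exposure$se,
                    by = by, sy = sy, eaf = exposure$eaf,
                    action = action, stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}

retained <- function(inst) {
  stopifnot(inherits(inst, "instrument_set"))
  inst[inst$action %in% c("kept", "flipped"), , drop = FALSE]
}

#' Inverse-variance weighted MR
#'
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`.  The default standard
#' error follows the multiplicative random-effects convention: the
#' fixed-effect SE is inflated by `sqrt(Q / (m - 1))`, floored at 1.  A
#' single retained variant degenerates to the Wald ratio `by/bx` with
#' SE `sy/|bx|`.
#'
#' @param inst an `instrument_set` from [harmonize()].
#' @param variance `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return an `mr_estimate` with heterogeneity Q.
#' @export
mr_ivw <- function(inst, variance = c("random", "fixed")) {
  variance <- match.arg(variance)
  d <- retained(inst)
  drop0 <- d$bx == 0
  if (any(drop0)) {
    warning(sprintf("excluding %d variant(s) with zero exposure effect",
                    sum(drop0)))
    d <- d[!drop0, , drop = FALSE]
  }
  m <- nrow(d)
  if (m < 1) stop("no usable instruments")
  if (m == 1)
    return(mr_estimate("ivw", d$by / d$bx, d$sy / abs(d$bx), 1))
  beta <- sum(d$bx * d$by / d$sy^2) / sum(d$bx^2 / d$sy^2)
  se_fixed <- 1 / sqrt(sum(d$bx^2 / d$sy^2))
  q <- sum((d$by - beta * d$bx)^2 / d$sy^2)
  se <- if (variance == "random") se_fixed * max(1, sqrt(q / (m - 1)))
        else se_fixed
  mr_estimate("ivw", beta, se, m, q = q, q_df = m - 1L)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept, weights `1/sy^2`, after orienting all exposure effects
#' positive.  The intercept tests directional pleiotropy; the slope is the
#' causal estimate.  SEs carry the multiplicative random-effects inflation
#' (residual SD floored at 1).
#'
#' @param inst an `instrument_set`.
#' @return list with `slope` and `intercept` `mr_estimate`s.
#' @export
mr_egger <- function(inst) {
  d <- retained(inst)
  m <- nrow(d)
  if (m < 3) stop("MR-Egger requires at least 3 variants")
  flip <- d$bx < 0
  bx <- abs(d$bx)
  by <- ifelse(flip, -d$by, d$by)
  if (diff(range(bx)) == 0)
    stop("no instrument-strength variation")
  w <- 1 / d$sy^2
  sw <- sum(w)
  mx <- sum(w * bx) / sw
  my <- sum(w * by) / sw
  sxx <- sum(w * (bx - mx)^2)
  slope <- sum(w * (bx - mx) * (by - my)) / sxx
  intercept <- my - slope * mx
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (m - 2)
  infl <- max(1, sqrt(sigma2))
  se_slope <- infl / sqrt(sxx)
  se_int <- infl * sqrt(1 / sw + mx^2 / sxx)
  list(slope = mr_estimate("egger_slope", slope, se_slope, m,
                           q = sum(w * resid^2), q_df = m - 2L),
       intercept = mr_estimate("egger_intercept", intercept, se_int, m))
}

# interpolated inverse-variance-weighted median of per-variant ratios at
# cumulative weight 0.5
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  pcum <- cumsum(w) - w / 2
  approx(pcum, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' The inverse-variance-weighted 50th percentile of the per-variant Wald
#' ratios, interpolated linearly between bracketing order statistics at
#' cumulative weight 0.5.  The SE comes from a seeded parametric bootstrap
#' resampling `bx` and `by` from their sampling distributions.
#'
#' @param inst an `instrument_set`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(inst, n_boot = 1000L, seed = 1L) {
  d <- retained(inst)
  d <- d[d$bx != 0, , drop = FALSE]
  m <- nrow(d)
  if (m < 3) stop("weighted median requires at least 3 variants")
  w <- d$bx^2 / d$sy^2
  est <- weighted_median_point(d$by / d$bx, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(m, d$bx, d$sx)
      by <- rnorm(m, d$by, d$sy)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / d$sy[ok]^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, sd(boots), m,
              extra = list(seed = seed, n_boot = n_boot))
}

#' Weighted-mode MR
#'
#' Kernel-density mode of the per-variant Wald ratios with inverse-variance
#' weights (normal kernel; modified Silverman bandwidth
#' `0.9 min(sd, mad) m^(-1/5)` times `bandwidth_factor`).  SE by seeded
#' parametric bootstrap.
#'
#' @param inst an `instrument_set`.
#' @param bandwidth_factor multiplier on the default bandwidth.
#' @param n_boot,seed bootstrap controls.
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(inst, bandwidth_factor = 1, n_boot = 1000L,
                             seed = 1L) {
  d <- retained(inst)
  d <- d[d$bx != 0, , drop = FALSE]
  m <- nrow(d)
  if (m < 3) stop("weighted mode requires at least 3 variants")
  mode_point <- function(bx, by, sy) {
    r <- by / bx
    w <- (bx / sy)^2
    w <- w / sum(w)
    spread <- min(sd(r), mad(r))
    if (!is.finite(spread) || spread == 0) return(r[1])
    h <- bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
    dens <- vapply(grid, function(g) sum(w * dnorm((g - r) / h)) / h,
                   numeric(1))
    grid[which.max(dens)]
  }
  est <- mode_point(d$bx, d$by, d$sy)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(m, d$bx, d$sx)
      by <- rnorm(m, d$by, d$sy)
      ok <- bx != 0
      mode_point(bx[ok], by[ok], d$sy[ok])
    }, numeric(1))
  })
  mr_estimate("weighted_mode", est, sd(boots), m,
              extra = list(seed = seed, n_boot = n_boot,
                           bandwidth_factor = bandwidth_factor))
}

#' Run all MR estimators
#'
#' @param inst an `instrument_set`.
#' @param methods subset of `ivw`, `egger`, `weighted_median`,
#'   `weighted_mode`.
#' @param seed seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates.
#' @return data frame with one row per method (Egger contributes slope and
#'   intercept rows): `method`, `beta`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `n_variants`.
#' @export
mr_all <- function(inst, methods = c("ivw", "egger", "weighted_median",
                                     "weighted_mode"),
                   seed = 1L, n_boot = 1000L) {
  ests <- list()
  if ("ivw" %in% methods) ests <- c(ests, list(mr_ivw(inst)))
  if ("egger" %in% methods) {
    eg <- mr_egger(inst)
    ests <- c(ests, list(eg$slope, eg$intercept))
  }
  if ("weighted_median" %in% methods)
    ests <- c(ests, list(mr_weighted_median(inst, n_boot, seed)))
  if ("weighted_mode" %in% methods)
    ests <- c(ests, list(mr_weighted_mode(inst, n_boot = n_boot,
                                          seed = seed)))
  do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               hr = exp(e$beta), ci_low = exp(e$ci_low),
               ci_high = exp(e$ci_high), p = e$p,
               n_variants = e$n_variants, stringsAsFactors = FALSE)
  }))
}

#' Hazard-ratio-scale report for an MR estimate
#'
#' @param est an `mr_estimate` on the log-hazard-per-SD scale.
#' @param per_unit also report per measurement unit, `HR^(1/sd_units)`.
#' @param sd_units units per SD (default 4.8 kg/m2 for BMI).
#' @return data frame with `scale`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
hr_per_sd <- function(est, per_unit = FALSE, sd_units = NULL) {
  stopifnot(inherits(est, "mr_estimate"))
  sd_units <- sd_units %||% est$sd_units
  out <- data.frame(method = est$method, scale = "per SD",
                    hr = exp(est$beta), ci_low = exp(est$ci_low),
                    ci_high = exp(est$ci_high), p = est$p,
                    stringsAsFactors = FALSE)
  if (per_unit) {
    out <- rbind(out, data.frame(
      method = est$method, scale = sprintf("per unit (SD = %g)", sd_units),
      hr = exp(est$beta / sd_units), ci_low = exp(est$ci_low / sd_units),
      ci_high = exp(est$ci_high / sd_units), p = est$p,
      stringsAsFactors = FALSE))
  }
  out
}

#' Z-test for interaction between subgroup estimates
#'
#' `z = (betaA - betaB) / sqrt(seA^2 + seB^2)`, two-sided normal p.
#'
#' @param a,b independent `mr_estimate`s (or lists with `beta` and `se`).
#' @return list with `z` and `p`.
#' @export
interaction_z <- function(a, b) {
  if (!is.finite(a$se) || !is.finite(b$se) || a$se <= 0 || b$se <= 0)
    stop("non-positive estimate variances")
  z <- (a$beta - b$beta) / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Per-variant instrument-validity heterogeneity test
#'
#' Two-group Cochran's Q (1 df) on the exposure effect of each instrument in
#' two populations, with a Bonferroni threshold `bonferroni_base / m`.  The
#' instrument is declared valid in the second group iff no variant is
#' flagged.
#'
#' @param stats1,stats2 `summary_stats` tables for the same instruments in
#'   the two groups.
#' @param bonferroni_base family-wise level (default 0.05).
#' @return list with the per-variant `table`, `threshold`, `n_flagged` and
#'   logical `valid`.
#' @export
instrument_validity_het <- function(stats1, stats2, bonferroni_base = 0.05) {
  ids <- intersect(stats1$variant_id, stats2$variant_id)
  m <- length(ids)
  if (m == 0) stop("no shared variants to test")
  s1 <- stats1[match(ids, stats1$variant_id), ]
  s2 <- stats2[match(ids, stats2$variant_id), ]
  q <- (s1$beta - s2$beta)^2 / (s1$se^2 + s2$se^2)
  p <- pchisq(q, 1, lower.tail = FALSE)
  threshold <- bonferroni_base / m
  tab <- data.frame(variant_id = ids, beta1 = s1$beta, beta2 = s2$beta,
                    q = q, p = p, flagged = p < threshold,
                    stringsAsFactors = FALSE)
  list(table = tab, threshold = threshold, n_flagged = sum(tab$flagged),
       valid = !any(tab$flagged))
}
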