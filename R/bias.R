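# Index-event (collider) bias correction for prognosis summary statistics.
#
# All scalar-slope methods estimate a bias slope b (prognosis effect per
# unit incidence effect) and return the affine-corrected statistics
# beta_adj = beta_prog - b * beta_inc with first-order propagated standard
# errors sqrt(se_prog^2 + b^2 * se_inc^2) (uncertainty in b itself is not
# propagated).

align_inc_prog <- function(incidence, prognosis, variants = NULL,
                           min_variants = 3) {
  ids <- intersect(incidence$variant_id, prognosis$variant_id)
  if (!is.null(variants)) ids <- intersect(ids, variants)
  inc <- incidence[match(ids, incidence$variant_id), ]
  prog <- prognosis[match(ids, prognosis$variant_id), ]
  keep <- (inc$estimable %||% TRUE) & (prog$estimable %||% TRUE) &
    is.finite(inc$beta) & is.finite(prog$beta) &
    is.finite(inc$se) & is.finite(prog$se) & inc$se > 0 & prog$se > 0
  inc <- inc[keep, ]
  prog <- prog[keep, ]
  if (nrow(inc) < min_variants)
    stop(sprintf("fewer than %d usable overlapping variants", min_variants))
  data.frame(variant_id = inc$variant_id, bI = inc$beta, seI = inc$se,
             bP = prog$beta, seP = prog$se, w = 1 / prog$se^2,
             stringsAsFactors = FALSE)
}

make_bias_adjustment <- function(method, b, se_b, cf, incidence, prognosis,
                                 cluster_assignments = NULL,
                                 per_start = NULL, extra = NULL) {
  ids <- intersect(incidence$variant_id, prognosis$variant_id)
  inc <- incidence[match(ids, incidence$variant_id), ]
  adj <- prognosis[match(ids, prognosis$variant_id), ]
  ok <- (inc$estimable %||% TRUE) & (adj$estimable %||% TRUE)
  adj$beta[ok] <- adj$beta[ok] - b * inc$beta[ok]
  adj$se[ok] <- sqrt(adj$se[ok]^2 + b^2 * inc$se[ok]^2)
  adj$pvalue[ok] <- wald_p(adj$beta[ok], adj$se[ok])
  rownames(adj) <- NULL
  class(adj) <- c("summary_stats", "data.frame")
  structure(list(method = method, b = b, se_b = se_b,
                 correction_factor = cf,
                 n_variants = sum(ok), adjusted = adj,
                 cluster_assignments = cluster_assignments,
                 per_start = per_start, extra = extra),
            class = "bias_adjustment")
}

#' Serialize a bias adjustment
#'
#' Writes the scalar summary (method, slope, SE, correction factor,
#' variant count) as a YAML block and, optionally, the bias-corrected
#' summary statistics as TSV.
#'
#' @param x a `bias_adjustment`.
#' @param path YAML output path.
#' @param stats_path optional TSV path for the adjusted statistics.
#' @export
write_bias_adjustment <- function(x, path, stats_path = NULL) {
  stopifnot(inherits(x, "bias_adjustment"))
  yaml::write_yaml(list(method = x$method, b = x$b, se_b = x$se_b,
                        correction_factor = x$correction_factor,
                        n_variants = x$n_variants), path, precision = 15)
  if (!is.null(stats_path)) write_summary_stats(x$adjusted, stats_path)
  invisible(path)
}

#' @export
print.bias_adjustment <- function(x, ...) {
  cat(sprintf("Index-event bias adjustment [%s]\n", x$method))
  cat(sprintf("  slope b = %.4f (se %.4f), correction factor %.4f, %d variants\n",
              x$b, x$se_b, x$correction_factor, x$n_variants))
  if (!is.null(x$per_start))
    cat(sprintf("  per-start slope range: [%.4f, %.4f] over %d starts\n",
                min(x$per_start$b), max(x$per_start$b), nrow(x$per_start)))
  invisible(x)
}

#' Raw weighted least-squares bias slope
#'
#' Weighted least-squares slope through the origin of prognosis effects on
#' incidence effects, with weights `1/se_prog^2`:
#' `b = sum(w bI bP) / sum(w bI^2)`.  No regression-dilution correction.
#'
#' @param incidence,prognosis `summary_stats` tables sharing variant ids.
#' @param variants optional ids restricting the estimation set (e.g.
#'   instruments); the affine correction is always applied to every
#'   overlapping variant.
#' @return class `bias_adjustment` with `method = "raw"`.
#' @export
raw_slope <- function(incidence, prognosis, variants = NULL) {
  d <- align_inc_prog(incidence, prognosis, variants)
  denom <- sum(d$w * d$bI^2)
  b <- sum(d$w * d$bI * d$bP) / denom
  se <- sqrt(1 / denom)
  make_bias_adjustment("raw", b, se, 1, incidence, prognosis)
}

cwls_core <- function(incidence, prognosis, variants) {
  d <- align_inc_prog(incidence, prognosis, variants)
  num <- sum(d$w * d$bI^2)
  den <- num - sum(d$w * d$seI^2)
  if (den <= 0) stop("incidence effects too weak to correct")
  cf <- num / den
  b_raw <- sum(d$w * d$bI * d$bP) / num
  list(b = cf * b_raw, se = cf * sqrt(1 / num), cf = cf, n = nrow(d))
}

#' Corrected weighted least squares (CWLS) bias adjustment
#'
#' The raw WLS slope is inflated by the Hedges-Olkin regression-dilution
#' correction factor `cf = sum(w bI^2) / (sum(w bI^2) - sum(w seI^2))`,
#' which undoes the attenuation caused by sampling error in the incidence
#' effects.
#'
#' @inheritParams raw_slope
#' @return class `bias_adjustment` with `method = "cwls"`.
#' @export
cwls_adjust <- function(incidence, prognosis, variants = NULL) {
  r <- cwls_core(incidence, prognosis, variants)
  make_bias_adjustment("cwls", r$b, r$se, r$cf, incidence, prognosis)
}

#' Dudbridge-style bias adjustment
#'
#' Weighted least-squares slope with Hedges-Olkin dilution correction,
#' algebraically the same estimator as [cwls_adjust()] under the default
#' configuration; it is kept as a separate entry point because the two are
#' used as distinct sensitivity analyses with their own provenance.
#'
#' @inheritParams raw_slope
#' @return class `bias_adjustment` with `method = "dudbridge"`.
#' @export
dudbridge_adjust <- function(incidence, prognosis, variants = NULL) {
  r <- cwls_core(incidence, prognosis, variants)
  make_bias_adjustment("dudbridge", r$b, r$se, r$cf, incidence, prognosis)
}

#' Traditional two-sample MR bias slope
#'
#' Estimates the bias slope as the IVW effect of incidence on prognosis
#' using incidence-significant variants as instruments (no dilution
#' correction; genome-wide-significant instruments make it negligible).
#'
#' @inheritParams raw_slope
#' @param p_threshold incidence significance threshold for instrument
#'   selection.
#' @return class `bias_adjustment` with `method = "mr_slope"`.
#' @export
mr_slope_adjust <- function(incidence, prognosis, p_threshold = 5e-8,
                            variants = NULL) {
  sig <- incidence$variant_id[incidence$pvalue < p_threshold &
                                (incidence$estimable %||% TRUE)]
  if (!is.null(variants)) sig <- intersect(sig, variants)
  if (length(sig) < 3)
    stop("fewer than 3 incidence-significant variants for the MR slope")
  d <- align_inc_prog(incidence, prognosis, sig)
  denom <- sum(d$w * d$bI^2)
  b <- sum(d$w * d$bI * d$bP) / denom
  se <- sqrt(1 / denom)
  make_bias_adjustment("mr_slope", b, se, 1, incidence, prognosis)
}

#' Slope-Hunter bias adjustment
#'
#' Two-component model-based clustering on the (incidence, prognosis) effect
#' pairs.  Class 1 collects variants affecting incidence only, whose
#' prognosis effects arise purely from selection: `bP = b * bI` up to
#' sampling error, with the conditional variance pinned to the known
#' sampling variances `seP^2 + b^2 seI^2`.  Class 2 is a free bivariate
#' normal absorbing variants with direct prognosis effects.  The bias slope
#' is taken from class 1.  EM is run from `n_starts + 2` initializations
#' (k-means on the standardized pairs, a dominant-class-1 start, random
#' responsibilities for the rest); the best log-likelihood wins, with
#' near-ties resolved toward the larger class-1 mass.  Per-start slopes are
#' returned so the method's instability is observable.
#'
#' @inheritParams raw_slope
#' @param n_starts number of EM initializations.
#' @param seed integer seed for the random starts.
#' @param max_iter,tol EM controls (log-likelihood convergence).
#' @return class `bias_adjustment` with `method = "slope_hunter"`,
#'   `cluster_assignments` (posterior probability of class 1) and
#'   `per_start`.
#' @export
slope_hunter <- function(incidence, prognosis, variants = NULL,
                         n_starts = 10L, seed = 1L, max_iter = 10000L,
                         tol = 1e-8) {
  d <- align_inc_prog(incidence, prognosis, variants, min_variants = 20)
  x <- d$bI
  y <- d$bP
  m <- length(x)

  # Class 1 (incidence-only variants): bP = b * bI up to SAMPLING error, so
  # its conditional variance is pinned to seP^2 + b^2 seI^2 rather than
  # estimated -- otherwise the free-covariance class 2 can mimic the line
  # exactly and the labels are unidentifiable.
  run_em <- function(g1) {
    pi1 <- mean(g1)
    b <- sum(g1 * x * y) / sum(g1 * x^2)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      s1 <- sum(g1)
      s2 <- m - s1
      if (s1 < 2 || s2 < 2) return(NULL)
      v1x <- sum(g1 * x^2) / s1
      v1y <- d$seP^2 + b^2 * d$seI^2
      w1 <- g1 / v1y
      b <- sum(w1 * x * y) / sum(w1 * x^2)
      S <- matrix(0, 2, 2)
      g2 <- 1 - g1
      S[1, 1] <- sum(g2 * x^2) / s2
      S[2, 2] <- sum(g2 * y^2) / s2
      S[1, 2] <- S[2, 1] <- sum(g2 * x * y) / s2
      # class-2 variants add direct-effect variance on top of sampling
      # noise, so its conditional variance may not undercut the class-1
      # sampling floor
      floor2 <- mean(v1y)
      if (S[1, 1] > 0 && S[2, 2] - S[1, 2]^2 / S[1, 1] < floor2)
        S[2, 2] <- S[1, 2]^2 / S[1, 1] + floor2
      detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
      if (v1x < 1e-300 || detS < 1e-300) return(NULL)
      l1 <- log(pi1) - 0.5 * log(2 * pi * v1x) - x^2 / (2 * v1x) -
        0.5 * log(2 * pi * v1y) - (y - b * x)^2 / (2 * v1y)
      Sinv <- solve(S)
      quad <- Sinv[1, 1] * x^2 + 2 * Sinv[1, 2] * x * y + Sinv[2, 2] * y^2
      l2 <- log(1 - pi1) - log(2 * pi) - 0.5 * log(detS) - quad / 2
      mx <- pmax(l1, l2)
      ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
      g1 <- 1 / (1 + exp(l2 - l1))
      pi1 <- mean(g1)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        return(list(ll = ll, b = b, g1 = g1, v1y = mean(v1y), pi1 = pi1,
                    converged = TRUE))
      }
      ll_old <- ll
    }
    list(ll = ll_old, b = b, g1 = g1, v1y = mean(v1y), pi1 = pi1,
         converged = FALSE)
  }

  inits <- with_seed(seed, {
    km <- tryCatch(kmeans(scale(cbind(x, y)), 2, nstart = 5)$cluster,
                   error = function(e) NULL)
    first <- if (is.null(km)) runif(m) else as.numeric(km == 1)
    # one start assuming a dominant incidence-only class, so that the
    # parsimonious labeling is always among the candidates
    c(list(first, rep(0.95, m)),
      lapply(seq_len(max(n_starts - 1, 0)), function(i) runif(m)))
  })
  fits <- lapply(inits, run_em)
  # explore the label-swapped basin of every converged start as well: with
  # a dominant line cluster the two labelings can tie in likelihood
  swapped <- lapply(fits, function(f) {
    if (is.null(f)) NULL else run_em(1 - f$g1)
  })
  fits <- c(fits, swapped)
  keep <- !vapply(fits, is.null, logical(1))
  all_degenerate <- !any(keep)
  if (all_degenerate) {
    # every two-component start collapsed a class below two expected
    # members: the data carry no separable second class, which is the
    # one-component (all incidence-only) limit fitted below
    fits <- list(list(ll = -Inf, b = NA_real_, g1 = rep(1, m),
                      v1y = NA_real_, pi1 = 1, converged = FALSE))
    keep <- TRUE
  }
  fits <- fits[keep]
  per_start <- data.frame(start = which(keep),
                          loglik = vapply(fits, `[[`, numeric(1), "ll"),
                          b = vapply(fits, `[[`, numeric(1), "b"),
                          converged = vapply(fits, `[[`, logical(1),
                                             "converged"))
  # label-swapped optima can tie in likelihood; among near-ties prefer the
  # solution whose line class carries more variants (the incidence-only
  # cluster should not be a sliver), then the purest line (smallest
  # residual variance)
  near <- which(per_start$loglik >= max(per_start$loglik) -
                  1e-6 * (1 + abs(max(per_start$loglik))))
  pi1 <- vapply(fits, `[[`, numeric(1), "pi1")
  v1y <- vapply(fits, `[[`, numeric(1), "v1y")
  hi <- near[pi1[near] >= max(pi1[near]) - 0.1]
  best <- fits[[hi[order(v1y[hi], na.last = TRUE)][1]]]
  # model selection against the degenerate one-component model in which
  # every variant is incidence-only: when all effect pairs lie on the line
  # up to sampling error the two-component labels are not identifiable,
  # and BIC prefers the parsimonious single class
  b1 <- sum(x * y / d$seP^2) / sum(x^2 / d$seP^2)
  for (it in 1:3) {
    v1 <- d$seP^2 + b1^2 * d$seI^2
    b1 <- sum(x * y / v1) / sum(x^2 / v1)
  }
  v1x1 <- mean(x^2)
  ll1 <- sum(dnorm(x, 0, sqrt(v1x1), log = TRUE) +
               dnorm(y, b1 * x, sqrt(v1), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(m)
  bic2 <- -2 * best$ll + 6 * log(m)
  if (bic1 <= bic2) {
    best <- list(ll = ll1, b = b1, g1 = rep(1, m), v1y = mean(v1),
                 pi1 = 1, converged = TRUE)
  }
  se_b <- sqrt(best$v1y / sum(best$g1 * x^2))
  adj <- make_bias_adjustment("slope_hunter", best$b, se_b, 1,
                              incidence, prognosis,
                              cluster_assignments =
                                setNames(best$g1, d$variant_id),
                              per_start = per_start)
  adj
}

#' Bivariate MR with corrected weighted least squares (CWBLS)
#'
#' Multivariable weighted least squares of prognosis effects on the two
#' columns (exposure effect, incidence effect) with weights `1/se_prog^2`,
#' solving measurement-error-corrected normal equations: the diagonal of the
#' weighted Gram matrix is debiased by the weighted sums of the regressor
#' sampling variances.  The exposure coefficient is the bias-adjusted causal
#' log-hazard per SD; the incidence coefficient is the bias slope.
#'
#' The estimating equations implemented here are the implementer's pinned
#' reading of corrected weighted least squares extended to two regressors
#' measured with independent error; standard errors are first-order
#' (`A^-1 B A^-1` with an overdispersion floor), ignoring error in the Gram
#' correction itself.
#'
#' The default variant set is the union of exposure instruments and
#' incidence instruments at `p_threshold`: with exposure instruments alone
#' the two regressor columns are proportional (instrument incidence effects
#' are mediated by the exposure) and the corrected Gram matrix is singular.
#'
#' @param exposure,incidence,prognosis `summary_stats` tables sharing
#'   variant ids.
#' @param p_threshold instrument-selection threshold for both traits.
#' @param variants optional explicit variant-id set overriding instrument
#'   selection.
#' @return list with `estimate` (an `mr_estimate` for the causal effect) and
#'   `adjustment` (a `bias_adjustment` with `method = "cwbls"`).
#' @export
cwbls_bivariate <- function(exposure, incidence, prognosis,
                            p_threshold = 5e-8, variants = NULL) {
  if (is.null(variants)) {
    vx <- exposure$variant_id[exposure$pvalue < p_threshold &
                                (exposure$estimable %||% TRUE)]
    vi <- incidence$variant_id[incidence$pvalue < p_threshold &
                                 (incidence$estimable %||% TRUE)]
    variants <- union(vx, vi)
  }
  ids <- Reduce(intersect, list(exposure$variant_id, incidence$variant_id,
                                prognosis$variant_id))
  ids <- intersect(ids, variants)
  ex <- exposure[match(ids, exposure$variant_id), ]
  inc <- incidence[match(ids, incidence$variant_id), ]
  prog <- prognosis[match(ids, prognosis$variant_id), ]
  keep <- (ex$estimable %||% TRUE) & (inc$estimable %||% TRUE) &
    (prog$estimable %||% TRUE) & prog$se > 0
  ex <- ex[keep, ]; inc <- inc[keep, ]; prog <- prog[keep, ]
  m <- nrow(ex)
  if (m < 4) stop("fewer than 4 usable variants for CWBLS")
  w <- 1 / prog$se^2
  B <- matrix(c(sum(w * ex$beta^2), sum(w * ex$beta * inc$beta),
                sum(w * ex$beta * inc$beta), sum(w * inc$beta^2)), 2, 2)
  A <- B - diag(c(sum(w * ex$se^2), sum(w * inc$se^2)))
  if (sum(w * inc$beta^2) < 1e-10 * sum(w * ex$beta^2)) {
    # degenerate incidence column: the bivariate model collapses to the
    # univariate corrected regression on the exposure effects
    theta1 <- sum(w * ex$beta * prog$beta) / A[1, 1]
    resid <- prog$beta - theta1 * ex$beta
    q <- sum(w * resid^2)
    scale2 <- max(1, q / (m - 1))
    est <- mr_estimate("cwbls", theta1,
                       sqrt(scale2 * B[1, 1]) / A[1, 1],
                       n_variants = m, q = q, q_df = m - 1)
    adj <- make_bias_adjustment("cwbls", 0, NA_real_, 1, incidence,
                                prognosis)
    return(list(estimate = est, adjustment = adj))
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("instruments too weak for CWBLS")
  cvec <- c(sum(w * ex$beta * prog$beta), sum(w * inc$beta * prog$beta))
  theta <- solve(A, cvec)
  resid <- prog$beta - theta[1] * ex$beta - theta[2] * inc$beta
  q <- sum(w * resid^2)
  scale2 <- max(1, q / (m - 2))
  Ainv <- solve(A)
  V <- scale2 * (Ainv %*% B %*% Ainv)
  est <- mr_estimate("cwbls", theta[1], sqrt(V[1, 1]), n_variants = m,
                     q = q, q_df = m - 2)
  adj <- make_bias_adjustment("cwbls", theta[2], sqrt(V[2, 2]), 1,
                              incidence, prognosis,
                              extra = list(theta = theta, vcov = V))
  list(estimate = est, adjustment = adj)
}
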