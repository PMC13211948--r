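# Restricted cubic splines (natural splines in truncated-power form) and BMI
# categorization.

rcs_columns <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1]
  norm <- (tk - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pp(x - tj) -
                       pp(x - tk1) * (tk - tj) / (tk - tk1) +
                       pp(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("x", seq_len(k - 2), "p"))
  out
}

#' Restricted cubic spline basis
#'
#' Builds the truncated-power restricted cubic (natural) spline basis with
#' knots at the given percentiles of `x`.  Knots use linear-interpolation
#' quantiles (R type 7); this rule is pinned because knot placement is
#' otherwise not reproducible across software.  With 4 knots the basis has 3
#' columns (a linear term plus two restricted cubic terms) and is exactly
#' linear beyond the boundary knots.
#'
#' @param x numeric vector with at least 20 distinct values.
#' @param percentiles knot locations as percentiles (default 5, 25, 75, 95).
#' @param ref reference value for hazard-ratio anchoring (default 25, the
#'   BMI normal/overweight boundary).
#' @return class `rcs_basis`: `knots`, `basis` (n x (k-1)), `percentiles`,
#'   `ref`.
#' @export
rcs_basis <- function(x, percentiles = c(5, 25, 75, 95), ref = 25) {
  if (length(unique(x)) < 20)
    stop("need at least 20 distinct values to place spline knots")
  knots <- unname(quantile(x, percentiles / 100, type = 7, names = FALSE))
  if (any(duplicated(knots)))
    stop("tied knots: x is too discrete for the requested percentiles")
  structure(list(knots = knots, basis = rcs_columns(x, knots),
                 percentiles = percentiles, ref = ref),
            class = "rcs_basis")
}

#' Evaluate a restricted cubic spline basis at new points
#'
#' @param object an `rcs_basis`.
#' @param newx points to evaluate at.
#' @return matrix with the same columns as `object$basis`.
#' @export
rcs_eval <- function(object, newx) {
  stopifnot(inherits(object, "rcs_basis"))
  rcs_columns(newx, object$knots)
}

#' Spline hazard-ratio curve from a Cox model
#'
#' Fits a Cox model on the restricted cubic spline basis of `x` (plus
#' optional covariates) and returns the hazard-ratio curve anchored at the
#' reference value, with delta-method confidence bands.
#'
#' @param time,event survival outcome as in [cox_fit()].
#' @param x continuous exposure (e.g. BMI, kg/m2).
#' @param covariates optional adjustment covariates.
#' @param ref anchor value (HR = 1 at `ref`).
#' @param grid evaluation points; default 100 points spanning the 1st-99th
#'   percentiles of `x`.
#' @param ... passed to [cox_fit()].
#' @return data frame `x`, `loghr`, `se`, `hr`, `ci_low`, `ci_high`; the fit
#'   is attached as attribute `fit`.
#' @export
rcs_cox_curve <- function(time, event, x, covariates = NULL, ref = 25,
                          grid = NULL, ...) {
  bas <- rcs_basis(x, ref = ref)
  X <- bas$basis
  if (!is.null(covariates)) {
    C <- as_covariate_matrix(covariates, length(x))
    X <- cbind(X, C)
  }
  fit <- cox_fit(time, event, X, ...)
  grid <- grid %||% seq(quantile(x, 0.01), quantile(x, 0.99),
                        length.out = 100)
  nb <- ncol(bas$basis)
  D <- rcs_eval(bas, grid) - rep(rcs_eval(bas, ref),
                                 each = length(grid))
  b <- fit$coefficients[seq_len(nb)]
  V <- fit$var[seq_len(nb), seq_len(nb), drop = FALSE]
  loghr <- drop(D %*% b)
  se <- sqrt(rowSums((D %*% V) * D))
  z <- z975()
  out <- data.frame(x = grid, loghr = loghr, se = se, hr = exp(loghr),
                    ci_low = exp(loghr - z * se),
                    ci_high = exp(loghr + z * se))
  attr(out, "fit") <- fit
  attr(out, "knots") <- bas$knots
  out
}

#' BMI category labels
#'
#' Standard six-category classification: underweight (< 18.5), normal
#' (18.5-24.9), overweight (25.0-29.9), class I obesity (30.0-34.9), class II
#' obesity (35.0-39.9) and class III obesity (>= 40 kg/m2).  Raw
#' floating-point values are compared against the thresholds (no rounding to
#' the printed precision), so e.g. 29.95 is overweight.
#'
#' @param bmi numeric vector, kg/m2, strictly positive.
#' @return factor with levels `underweight`, `normal`, `overweight`,
#'   `obesity_1`, `obesity_2`, `obesity_3`.
#' @export
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be positive and finite")
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obesity_1",
                 "obesity_2", "obesity_3"))
}
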