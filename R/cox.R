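# Cox proportional hazards fitting by Newton-Raphson maximization of the
# partial likelihood, with Efron (default) or Breslow tie handling.

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the Cox partial likelihood with
#' step-halving.  Convergence is declared when the largest score component
#' falls below `tol_score` or the relative log-likelihood change falls below
#' `tol_loglik`.  The covariance is the inverse observed information.
#' Monotone (infinite) likelihoods are detected and flagged rather than
#' reported as converged estimates.
#'
#' @param time follow-up times (stop times when `start` is given).
#' @param event 0/1 (or logical) event indicator.
#' @param covariates numeric matrix, data frame or vector.
#' @param ties `"efron"` (default) or `"breslow"`.  Identical on untied data.
#' @param weights optional case weights.
#' @param start optional entry times for delayed-entry (start, stop] risk
#'   sets.
#' @param init initial coefficient values (default 0).
#' @param maxit,tol_score,tol_loglik iteration controls.
#' @return an object of class `cox_fit` with elements `coefficients`, `var`,
#'   `se`, `loglik` (first and final), `loglik_trace`, `score`, `n`,
#'   `n_events`, `iter`, `converged`, `monotone`, `ties`, `method`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow"),
                    weights = NULL, start = NULL, init = NULL, maxit = 50L,
                    tol_score = 1e-8, tol_loglik = 1e-10) {
  ties <- match.arg(ties)
  n <- length(time)
  X <- as_covariate_matrix(covariates, n)
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  if (sum(event) < 1) stop("at least one event is required")
  if (any(!is.finite(time)) || any(time < 0)) stop("negative times")
  if (!is.null(start)) {
    if (length(start) != n) stop("start and time lengths differ")
    if (any(start >= time)) stop("start times must precede stop times")
  }
  const <- which(apply(X, 2, function(z) diff(range(z)) == 0))
  if (length(const) > 0)
    stop(sprintf("constant covariate(s): %s",
                 paste(colnames(X)[const], collapse = ", ")))
  weights <- weights %||% rep(1, n)
  if (any(weights < 0)) stop("weights must be >= 0")
  init <- init %||% numeric(ncol(X))
  fit <- cox_fit_cpp(start %||% numeric(0), as.numeric(time), event,
                     X, as.numeric(weights), ties == "efron",
                     as.numeric(init), as.integer(maxit), tol_score,
                     tol_loglik)
  beta <- as.numeric(fit$coefficients)
  names(beta) <- colnames(X)
  V <- fit$var
  dimnames(V) <- list(colnames(X), colnames(X))
  trace <- as.numeric(fit$loglik_trace)
  structure(list(
    coefficients = beta, var = V, se = sqrt(diag(V)),
    loglik = c(init = trace[1], final = trace[length(trace)]),
    loglik_trace = trace, score = as.numeric(fit$score),
    n = n, n_events = sum(event), iter = fit$iter,
    converged = fit$converged, monotone = fit$monotone,
    singular = fit$singular, ties = ties, method = "cox"),
    class = "cox_fit")
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' Fit summary on the hazard-ratio scale
#'
#' @param fit a `cox_fit`.
#' @return data frame with one row per term: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
fit_summary_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  z <- z975()
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients), se = unname(fit$se),
             hr = exp(unname(fit$coefficients)),
             ci_low = exp(unname(fit$coefficients) - z * unname(fit$se)),
             ci_high = exp(unname(fit$coefficients) + z * unname(fit$se)),
             p = wald_p(unname(fit$coefficients), unname(fit$se)),
             stringsAsFactors = FALSE)
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model (%s ties): %d observations, %d events\n",
              if (x$method == "fine_gray") "Fine-Gray" else "Cox",
              x$ties, x$n, x$n_events))
  if (x$monotone)
    cat("  WARNING: monotone partial likelihood (separation); estimates diverge\n")
  else if (!x$converged)
    cat("  WARNING: did not converge\n")
  print(format(fit_summary_table(x), digits = digits), row.names = FALSE)
  cat(sprintf("partial loglik: %.*f (iter %d)\n", 3, x$loglik["final"],
              x$iter))
  invisible(x)
}

#' Scaled Schoenfeld residuals and proportional-hazards test
#'
#' Per-event residuals `x_k - xbar(t_k)` at the fitted coefficients, scaled
#' by `n_events * vcov(fit)` and shifted by the coefficient (Grambsch-
#' Therneau scaling).  The proportionality test correlates each scaled
#' residual series with the rank of the event time (Pearson, t-test).
#'
#' @param fit a converged `cox_fit` (no delayed entry).
#' @param time,event,covariates the data the model was fitted to.
#' @return class `schoenfeld_test`: event times, residual and scaled
#'   residual matrices, per-covariate correlation and p-value.
#' @export
schoenfeld_scaled <- function(fit, time, event, covariates) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("fit did not converge")
  n <- length(time)
  X <- as_covariate_matrix(covariates, n)
  event <- as.integer(event)
  if (sum(event) < 3) stop("fewer than 3 events: residual test undefined")
  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  w <- exp(eta - max(eta))
  o <- order(time)
  ts <- time[o]
  ws <- w[o]
  Xs <- X[o, , drop = FALSE]
  ev <- event[o]
  # risk-set sums: S0(t) and S1(t) via reverse cumulative sums; tied times
  # share the risk set of the first member of the tie group
  rc0 <- rev(cumsum(rev(ws)))
  first <- match(ts, ts)
  S0 <- rc0[first]
  xbar <- matrix(0, n, ncol(X))
  for (j in seq_len(ncol(X))) {
    rc1 <- rev(cumsum(rev(ws * Xs[, j])))
    xbar[, j] <- rc1[first] / S0
  }
  ke <- which(ev == 1L)
  res <- Xs[ke, , drop = FALSE] - xbar[ke, , drop = FALSE]
  d <- length(ke)
  scaled <- sweep(res %*% (d * fit$var), 2, beta, `+`)
  colnames(res) <- colnames(scaled) <- colnames(X)
  tev <- ts[ke]
  rk <- rank(tev)
  cors <- ps <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    y <- scaled[, j]
    if (sd(y) > 0) {
      r <- cor(rk, y)
      tt <- r * sqrt((d - 2) / (1 - r^2))
      cors[j] <- r
      ps[j] <- 2 * stats::pt(-abs(tt), d - 2)
    }
  }
  structure(list(time = tev, residuals = res, scaled = scaled,
                 correlation = cors, p = ps),
            class = "schoenfeld_test")
}

#' @export
print.schoenfeld_test <- function(x, ...) {
  cat("Scaled Schoenfeld proportional-hazards test\n")
  print(data.frame(correlation = x$correlation, p = x$p))
  invisible(x)
}
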