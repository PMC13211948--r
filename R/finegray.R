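# Fine-Gray subdistribution hazards: a weighted Cox fit in which individuals
# failing from the competing cause remain in the risk set with
# inverse-probability-of-censoring weights from the Kaplan-Meier estimate of
# the censoring distribution (Fine & Gray 1999 convention).

# Kaplan-Meier of the censoring distribution; returns a left-continuous
# evaluator G(t-).
censoring_km <- function(time, censored) {
  o <- order(time)
  ts <- time[o]
  cs <- censored[o]
  ut <- unique(ts[cs == 1L])
  if (length(ut) == 0) {
    return(function(t) rep(1, length(t)))
  }
  n_at_risk <- vapply(ut, function(u) sum(ts >= u), numeric(1))
  d <- vapply(ut, function(u) sum(ts == u & cs == 1L), numeric(1))
  surv <- cumprod(1 - d / n_at_risk)
  function(t) {
    idx <- findInterval(t, ut, left.open = TRUE)  # strictly before t
    ifelse(idx == 0, 1, surv[pmax(idx, 1)])
  }
}

normalize_competing_event <- function(event) {
  if (is.factor(event) || is.character(event)) {
    event <- as.character(event)
    ok <- event %in% c("primary", "competing", "censored")
    if (!all(ok)) stop("event labels must be primary/competing/censored")
    match(event, c("censored", "primary", "competing")) - 1L
  } else {
    event <- as.integer(event)
    if (!all(event %in% 0:2))
      stop("integer event codes must be 0 (censored), 1 (primary), 2 (competing)")
    event
  }
}

#' Fine-Gray subdistribution hazard model
#'
#' Fits the subdistribution hazard of the primary event with the competing
#' cause handled by keeping competing failures in later risk sets, weighted
#' by `G(t-)/G(T_i-)` where `G` is the Kaplan-Meier of the censoring
#' distribution.  The expanded (start, stop] data are fitted with the same
#' partial-likelihood core as [cox_fit()] (Breslow ties); the reported
#' covariance is a robust (infinitesimal-jackknife) sandwich grouped by
#' individual, treating the censoring weights as fixed.
#'
#' With no competing events the expansion is empty and the coefficients
#' coincide with [cox_fit()].
#'
#' @param time follow-up times.
#' @param event `"primary"` / `"competing"` / `"censored"` factor or
#'   character, or integer codes 1 / 2 / 0.
#' @param covariates numeric matrix, data frame or vector.
#' @return a `cox_fit` object with `method = "fine_gray"` and robust `var`.
#' @export
fine_gray_fit <- function(time, event, covariates) {
  n <- length(time)
  ev <- normalize_competing_event(event)
  X <- as_covariate_matrix(covariates, n)
  if (sum(ev == 1L) < 1) stop("at least one primary event is required")
  if (any(!is.finite(time)) || any(time < 0)) stop("negative times")
  const <- which(apply(X, 2, function(z) diff(range(z)) == 0))
  if (length(const) > 0)
    stop(sprintf("constant covariate(s): %s",
                 paste(colnames(X)[const], collapse = ", ")))

  G <- censoring_km(time, as.integer(ev == 0L))
  pt <- sort(unique(time[ev == 1L]))

  # base rows: everyone contributes (0, T_i] with weight 1
  start <- rep(0, n)
  stop_ <- time
  status <- as.integer(ev == 1L)
  wt <- rep(1, n)
  id <- seq_len(n)

  comp <- which(ev == 2L)
  if (length(comp) > 0) {
    ex_start <- ex_stop <- ex_w <- numeric(0)
    ex_id <- integer(0)
    for (i in comp) {
      later <- pt[pt > time[i]]
      if (length(later) == 0) next
      s <- c(time[i], later[-length(later)])
      w <- G(later) / G(time[i])
      keep <- w > 0
      ex_start <- c(ex_start, s[keep])
      ex_stop <- c(ex_stop, later[keep])
      ex_w <- c(ex_w, w[keep])
      ex_id <- c(ex_id, rep(i, sum(keep)))
    }
    start <- c(start, ex_start)
    stop_ <- c(stop_, ex_stop)
    status <- c(status, rep(0L, length(ex_stop)))
    wt <- c(wt, ex_w)
    id <- c(id, ex_id)
  }
  Xe <- X[id, , drop = FALSE]

  fit <- cox_fit_cpp(start, stop_, status, Xe, wt, FALSE,
                     numeric(ncol(X)), 50L, 1e-8, 1e-10)
  beta <- as.numeric(fit$coefficients)
  names(beta) <- colnames(X)
  Vmod <- fit$imat
  Vinv <- solve(Vmod)

  # grouped score residuals -> sandwich variance
  rs <- cox_riskset_stats_cpp(start, stop_, status, Xe, wt, beta)
  # event-time stats come ordered by decreasing time; flip ascending
  ord <- order(rs$time)
  tk <- rs$time[ord]
  dlam <- (rs$dwk / rs$s0)[ord]
  xbar <- rs$xbar[ord, , drop = FALSE]
  cumA <- cumsum(dlam)
  cumB <- apply(xbar * dlam, 2, cumsum)
  if (length(tk) == 1) cumB <- matrix(cumB, nrow = 1)
  idx_stop <- findInterval(stop_, tk)            # t_k <= stop
  idx_start <- findInterval(start, tk)           # t_k <= start (to subtract)
  eta <- pmin(pmax(drop(Xe %*% beta), -500), 500)  # as in the fitting core
  ew <- wt * exp(eta)
  lookA <- function(i) ifelse(i == 0, 0, cumA[pmax(i, 1)])
  lookB <- function(i) {
    out <- matrix(0, length(i), ncol(Xe))
    pos <- i > 0
    out[pos, ] <- cumB[i[pos], , drop = FALSE]
    out
  }
  A <- lookA(idx_stop) - lookA(idx_start)
  B <- lookB(idx_stop) - lookB(idx_start)
  ev_xbar <- matrix(0, length(stop_), ncol(Xe))
  ke <- which(status == 1L)
  ev_xbar[ke, ] <- xbar[match(stop_[ke], tk), , drop = FALSE]
  U <- wt * status * (Xe - ev_xbar) - ew * (Xe * A - B)
  Ug <- rowsum(U, id)
  meat <- crossprod(Ug)
  Vrob <- Vinv %*% meat %*% Vinv
  dimnames(Vrob) <- list(colnames(X), colnames(X))

  trace <- as.numeric(fit$loglik_trace)
  structure(list(
    coefficients = beta, var = Vrob, se = sqrt(diag(Vrob)),
    var_model = solve(Vmod),
    loglik = c(init = trace[1], final = trace[length(trace)]),
    loglik_trace = trace, score = as.numeric(fit$score),
    n = n, n_events = sum(ev == 1L), n_competing = sum(ev == 2L),
    iter = fit$iter, converged = fit$converged, monotone = fit$monotone,
    singular = fit$singular, ties = "breslow", method = "fine_gray"),
    class = "cox_fit")
}
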