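# internal helpers

# Deterministic per-stage sub-seeds derived from one user seed, so that e.g.
# adding variants does not perturb the survival draws.  Kept < 2^31 - 1.
stage_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stage) * 104729
  as.integer(s %% 2147483629 + 1)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

z975 <- function() qnorm(0.975)

# two-sided normal p from estimate and SE
wald_p <- function(beta, se) 2 * pnorm(-abs(beta / se))

as_covariate_matrix <- function(covariates, n, arg = "covariates") {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (is.vector(covariates) && is.numeric(covariates)) {
    covariates <- matrix(covariates, ncol = 1,
                         dimnames = list(NULL, "x"))
  }
  if (!is.matrix(covariates) || !is.numeric(covariates))
    stop(sprintf("'%s' must be a numeric matrix, data frame or vector", arg))
  if (nrow(covariates) != n)
    stop(sprintf("'%s' has %d rows but %d are required", arg,
                 nrow(covariates), n))
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (any(!is.finite(covariates)))
    stop(sprintf("'%s' contains non-finite values", arg))
  covariates
}
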