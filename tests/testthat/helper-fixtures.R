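# shared fixture builders and independent oracles

# a summary_stats table from raw vectors
make_stats <- function(beta, se, ids = paste0("v", seq_along(beta)),
                       eaf = 0.3, n = 1000, chrom = 1L,
                       pos = seq_along(beta) * 11e6,
                       ea = "A", oa = "G") {
  d <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                  effect_allele = ea, other_allele = oa, eaf = eaf,
                  beta = beta, se = se,
                  pvalue = 2 * pnorm(-abs(beta / se)), n = n,
                  estimable = TRUE, stringsAsFactors = FALSE)
  class(d) <- c("summary_stats", "data.frame")
  d
}

# an instrument_set from raw vectors
make_instruments <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                             eaf = 0.3) {
  d <- data.frame(variant_id = paste0("v", seq_along(bx)), bx = bx,
                  sx = sx, by = by, sy = sy, eaf = eaf, action = "kept",
                  stringsAsFactors = FALSE)
  class(d) <- c("instrument_set", "data.frame")
  d
}

# independent grid-search maximizer of the written-out Cox partial
# likelihood (Breslow form; intended for untied data), one covariate
cox_grid_oracle <- function(time, event, x, grid = seq(-2, 2, by = 1e-4)) {
  pl <- function(beta) {
    eta <- beta * x
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + eta[i] - log(sum(exp(eta[risk])))
    }
    s
  }
  lls <- vapply(grid, pl, numeric(1))
  grid[which.max(lls)]
}

# all-pairs LD pruning oracle: keep a variant iff it has r2 < r2_max with
# every retained better-ranked variant in the window
ld_prune_oracle <- function(stats, ref, r2_max = 0.001, window_kb = 10000) {
  o <- order(stats$pvalue, stats$chrom, stats$pos)
  st <- stats[o, ]
  kept <- character(0)
  for (i in seq_len(nrow(st))) {
    ok <- TRUE
    for (k in kept) {
      j <- which(st$variant_id == k)
      if (st$chrom[j] != st$chrom[i]) next
      if (abs(st$pos[j] - st$pos[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(ref[, st$variant_id[i]],
                                ref[, st$variant_id[j]]))
      if (is.finite(r) && r^2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, st$variant_id[i])
  }
  kept
}

# exhaustive cumulative-weight scan for the interpolated weighted median
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(r[1])
  for (i in seq_len(length(r) - 1)) {
    if (p[i] <= 0.5 && p[i + 1] >= 0.5) {
      return(r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  r[length(r)]
}

# small cohort for fast unit tests
small_cohort <- function(seed = 1, n = 4000, m = 60) {
  simulate_cohort(simulation_config(n_individuals = n, n_variants = m,
                                    seed = seed))
}
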