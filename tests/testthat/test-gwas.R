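test_that("fixed-effects meta-analysis matches hand-computed closed forms", {
  m <- fixed_effect_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(m$beta, 0.2)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(m$q, 2)
  expect_equal(m$df, 1L)
  expect_equal(sum(m$weights), 1)
  # identical studies: pooled equals each, Q = 0
  m2 <- fixed_effect_meta(c(0.15, 0.15, 0.15), c(0.2, 0.2, 0.2))
  expect_equal(m2$beta, 0.15)
  expect_equal(m2$q, 0)
  # one enormous se: weight limit
  m3 <- fixed_effect_meta(c(0.1, 5), c(0.1, 1e6))
  expect_equal(m3$beta, 0.1, tolerance = 1e-6)
  expect_error(fixed_effect_meta(0.1, 0.1), "at least 2 studies")
  # K identical studies shrink the se by sqrt(K)
  m4 <- fixed_effect_meta(rep(0.1, 9), rep(0.3, 9))
  expect_equal(m4$se, 0.3 / 3, tolerance = 1e-12)
})

test_that("fixed-effects meta-analysis agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(50)
  b <- rnorm(6, 0.2, 0.1)
  se <- runif(6, 0.05, 0.3)
  m1 <- fixed_effect_meta(b, se)
  m2 <- metafor::rma(yi = b, sei = se, method = "FE")
  expect_equal(m1$beta, as.numeric(m2$beta), tolerance = 1e-10)
  expect_equal(m1$se, as.numeric(m2$se), tolerance = 1e-10)
  expect_equal(m1$q, as.numeric(m2$QE), tolerance = 1e-10)
})

test_that("meta_summary_stats keeps only variants present in two or more studies", {
  s1 <- make_stats(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1))
  s2 <- make_stats(c(0.3, 0.1), c(0.1, 0.1), ids = c("v1", "v2"))
  s1$estimable[3] <- FALSE
  mm <- meta_summary_stats(list(s1, s2))
  expect_equal(mm$variant_id, c("v1", "v2"))
  expect_equal(mm$beta[1], 0.2)
  expect_equal(mm$n_studies, c(2L, 2L))
  expect_true(all(c("q_stat", "q_p") %in% names(mm)))
})

test_that("per-variant Cox scan is calibrated under the null", {
  # one cohort, many null variants: the empirical rejection rate across
  # null scans estimates the per-test type-I error
  cfg <- simulation_config(n_individuals = 2000, n_variants = 400,
                           variant_effects = 0,
                           onset_variant_effects = 0, seed = 51)
  co <- simulate_cohort(cfg)
  st <- build_summary_stats(co, "prognosis")
  rate <- mean(st$pvalue[st$estimable] < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.085)
  # dosage constant: non-estimable
  g <- attr(co, "genotypes")
  g[, 1] <- 1L
  attr(co, "genotypes") <- g
  expect_false(build_summary_stats(co, "prognosis")$estimable[1])
})

test_that("marginal per-variant hazard scans attenuate mildly under frailty", {
  # no selection: every individual is a case, but the scan marginalizes
  # over the strong latent severity, so per-variant effects shrink a few
  # percent toward the null (hazard-ratio non-collapsibility)
  shrinks <- vapply(6001:6006, function(s) {
    cfg <- simulation_config(n_individuals = 50000, n_variants = 20,
                             n_exposure_causal = 20, n_onset_causal = 0,
                             exposure_h2 = 0.5, onset_intercept = 20,
                             onset_beta_exposure = 0,
                             onset_beta_competitor = 0,
                             onset_beta_severity = 0, seed = s)
    co <- simulate_cohort(cfg)
    prog <- build_summary_stats(co, "prognosis")
    a <- attr(co, "effects_std")
    w <- 1 / prog$se^2
    recovered <- sum(w * a * prog$beta) / sum(w * a^2)
    recovered / attr(co, "config")$prognosis_loghr_exposure
  }, numeric(1))
  expect_gt(mean(shrinks), 0.78)
  expect_lt(mean(shrinks), 1.03)
})

test_that("greedy LD pruning handles windows, ties and matches the all-pairs oracle", {
  set.seed(52)
  n <- 400
  # same chromosome: perfectly correlated pair, best p wins
  g1 <- rbinom(n, 2, 0.3)
  ref <- cbind(v1 = g1, v2 = g1)
  st <- data.frame(variant_id = c("v1", "v2"), chrom = 1L,
                   pos = c(1e6, 2e6), pvalue = c(1e-9, 1e-8))
  expect_equal(ld_prune(st, ref)$variant_id, "v1")
  # same pair on different chromosomes: both retained
  st2 <- st
  st2$chrom <- c(1L, 2L)
  expect_equal(sort(ld_prune(st2, ref)$variant_id), c("v1", "v2"))
  # correlated block fixture vs exhaustive oracle
  m <- 50
  base <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  idx <- sample(1:5, m, replace = TRUE)
  noise <- matrix(rbinom(n * m, 2, 0.3), n, m)
  flip <- matrix(runif(n * m) < 0.4, n, m)
  G <- base[, idx]
  G[flip] <- noise[flip]
  colnames(G) <- paste0("v", 1:m)
  st3 <- data.frame(variant_id = paste0("v", 1:m),
                    chrom = rep(1:2, length.out = m),
                    pos = rep(seq(1e6, 9e6, length.out = 25), 2),
                    pvalue = runif(m))
  r2 <- 0.05  # loose threshold so the correlated block actually matters
  got <- ld_prune(st3, G, r2_max = r2)$variant_id
  expect_setequal(got, ld_prune_oracle(st3, G, r2_max = r2))
  # order invariance
  got2 <- ld_prune(st3[sample(m), ], G, r2_max = r2)$variant_id
  expect_equal(got, got2)
  expect_error(ld_prune(st3[, -1], G), "missing column")
  expect_error(ld_prune(st3, G[, 1:10]), "missing variant")
})

test_that("power-adjusted replication has the stated closed-form expectations", {
  # null discovery effects: expected replications = m * alpha
  disc <- make_stats(rep(0, 40), rep(0.1, 40))
  outc <- make_stats(rnorm(40, 0, 0.1), rep(0.1, 40))
  r <- power_adjusted_replication(disc, outc, alpha = 0.05)
  expect_equal(r$expected, 40 * 0.05, tolerance = 1e-10)
  # |b|/se at the significance boundary: power ~ 0.5
  disc1 <- make_stats(qnorm(0.975) * 0.1, 0.05, ids = "v1")
  outc1 <- make_stats(0.1, 0.1, ids = "v1")
  r1 <- power_adjusted_replication(disc1, outc1)
  expect_equal(r1$expected, 0.5, tolerance = 0.01)
  # unmatched variants excluded with warning
  disc2 <- make_stats(c(0.2, 0.2), c(0.05, 0.05))
  outc2 <- make_stats(0.2, 0.05, ids = "v1")
  expect_warning(r2 <- power_adjusted_replication(disc2, outc2),
                 "unmatched")
  expect_equal(r2$n, 1)
})

test_that("replication counts are self-consistent when effects transfer", {
  set.seed(53)
  m <- 60
  obs <- exp_cnt <- numeric(60)
  for (i in 1:60) {
    bd <- rnorm(m, 0, 0.15)
    se_o <- rep(0.08, m)
    bo <- rnorm(m, bd, se_o)
    disc <- make_stats(bd, rep(0.01, m))
    outc <- make_stats(bo, se_o)
    r <- power_adjusted_replication(disc, outc)
    obs[i] <- r$observed
    exp_cnt[i] <- r$expected
  }
  # observed ~ expected within binomial error of the replicate mean
  expect_lt(abs(mean(obs) - mean(exp_cnt)),
            3 * sd(obs) / sqrt(60) + 0.5)
})

test_that("suggestive_hits filters, prunes and nests monotonically", {
  st <- make_stats(rep(0, 10), rep(0.1, 10))
  st$pvalue <- 1
  ref <- matrix(rbinom(2000, 2, 0.3), 200, 10,
                dimnames = list(NULL, st$variant_id))
  expect_equal(nrow(suggestive_hits(st, ref)), 0)
  # three independent signals below threshold
  st2 <- st
  st2$pvalue[c(1, 4, 8)] <- c(1e-7, 1e-8, 4e-6)
  st2$chrom <- rep(1:5, each = 2)
  hits <- suggestive_hits(st2, ref, threshold = 5e-6)
  expect_setequal(hits$variant_id, c("v1", "v4", "v8"))
  strict <- suggestive_hits(st2, ref, threshold = 5e-8)
  expect_true(all(strict$variant_id %in% hits$variant_id))
})
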