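test_that("harmonization aligns alleles per the enumerated truth table", {
  ex <- make_stats(rep(0.2, 6), rep(0.01, 6),
                   ea = c("A", "A", "A", "A", "A", "A"),
                   oa = c("G", "G", "G", "T", "G", "G"))
  ex$eaf <- c(0.3, 0.3, 0.3, 0.50, 0.3, 0.3)
  out <- make_stats(c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3), rep(0.05, 6),
                    ea = c("A", "G", "T", "A", "A", "A"),
                    oa = c("G", "A", "C", "T", "C", "G"))
  out <- out[-6, ]  # v6 missing from the outcome
  inst <- suppressWarnings(harmonize(ex, out, p_threshold = NULL))
  expect_equal(inst$action,
               c("kept",                # direct match
                 "flipped",             # swapped alleles
                 "kept",                # strand complement T/C -> A/G
                 "dropped_palindromic", # A/T at eaf 0.50
                 "dropped_missing",     # A/C irreconcilable with A/G
                 "dropped_missing"))    # absent from outcome
  expect_equal(inst$by[1:3], c(0.3, -0.3, 0.3))
  # warnings name the irreconcilable variants
  expect_warning(harmonize(ex, out, p_threshold = NULL), "v5")
})

test_that("harmonization respects the instrument significance threshold", {
  ex <- make_stats(c(0.2, 0.001), c(0.01, 0.01))
  out <- make_stats(c(0.1, 0.1), c(0.05, 0.05))
  inst <- harmonize(ex, out, p_threshold = 5e-8)
  expect_equal(nrow(inst), 1)
  expect_error(harmonize(ex[2, , drop = FALSE], out), "no exposure")
})

test_that("IVW matches closed forms and degenerates to the Wald ratio", {
  i1 <- make_instruments(bx = 0.5, by = 0.2, sy = 0.1)
  e1 <- mr_ivw(i1)
  expect_equal(e1$beta, 0.4)
  expect_equal(e1$se, 0.2)
  i2 <- make_instruments(bx = c(1, 1), by = c(0.1, 0.3),
                         sy = c(0.1, 0.1))
  expect_equal(mr_ivw(i2)$beta, 0.2)
  # zero-bx instruments excluded with warning
  i3 <- make_instruments(bx = c(1, 1, 0), by = c(0.1, 0.3, 5),
                         sy = rep(0.1, 3))
  expect_warning(e3 <- mr_ivw(i3), "zero exposure effect")
  expect_equal(e3$beta, 0.2)
  # fixed vs random: random never smaller
  set.seed(70)
  i4 <- make_instruments(bx = runif(10, 0.1, 0.3),
                         by = rnorm(10, 0.05, 0.1),
                         sy = rep(0.05, 10))
  expect_gte(mr_ivw(i4)$se, mr_ivw(i4, variance = "fixed")$se)
})

test_that("IVW type-I error is calibrated under the null", {
  set.seed(71)
  rej <- replicate(500, {
    m <- 20
    bx <- rnorm(m, 0.12, 0.02)
    sy <- rep(0.04, m)
    inst <- make_instruments(bx, rnorm(m, 0, sy), sy,
                             sx = rep(0.007, m))
    mr_ivw(inst)$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("MR-Egger recovers exact linear structure and flags no-spread inputs", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  inst <- make_instruments(bx, by = 0.05 + 0.7 * bx, sy = rep(0.1, 5))
  eg <- mr_egger(inst)
  expect_equal(eg$slope$beta, 0.7, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.05, tolerance = 1e-10)
  flat <- make_instruments(rep(0.2, 4), rnorm(4), rep(0.1, 4))
  expect_error(mr_egger(flat), "no instrument-strength variation")
  expect_error(mr_egger(inst[1:2, ]), "at least 3")
})

test_that("MR-Egger separates directional pleiotropy from the causal slope", {
  set.seed(72)
  reps <- replicate(100, {
    m <- 30
    bx <- runif(m, 0.05, 0.3)
    by <- 0.05 + 0.3 * bx + rnorm(m, 0, 0.02)
    inst <- make_instruments(bx, by, rep(0.02, m))
    eg <- mr_egger(inst)
    c(eg$slope$beta, eg$intercept$beta)
  })
  expect_lt(abs(mean(reps[1, ]) - 0.3), 0.02)
  expect_lt(abs(mean(reps[2, ]) - 0.05), 0.005)
})

test_that("weighted median interpolates at cumulative weight one half", {
  inst <- make_instruments(rep(1, 3), c(0.1, 0.2, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(inst, n_boot = 50, seed = 1)$beta, 0.2)
  # weight concentrating on one variant pulls the estimate to its ratio
  inst2 <- make_instruments(rep(1, 3), c(0.1, 0.5, 0.9),
                            c(1e-4, 1, 1))
  expect_equal(mr_weighted_median(inst2, n_boot = 50, seed = 1)$beta, 0.1,
               tolerance = 0.01)
  # matches the exhaustive cumulative-weight scan on random fixtures
  set.seed(73)
  for (i in 1:20) {
    m <- 3 + i
    bx <- runif(m, 0.1, 0.5)
    sy <- runif(m, 0.02, 0.2)
    by <- rnorm(m, 0.2 * bx, sy)
    inst <- make_instruments(bx, by, sy)
    got <- mr_weighted_median(inst, n_boot = 2, seed = 1)$beta
    expect_equal(got, weighted_median_oracle(by / bx, bx^2 / sy^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median resists 30% invalid instruments better than IVW", {
  set.seed(74)
  wins <- replicate(100, {
    m <- 30
    bx <- runif(m, 0.1, 0.3)
    sy <- rep(0.02, m)
    pleio <- c(rep(0.15, 9), rep(0, 21))  # 30% invalid, large pleiotropy
    by <- rnorm(m, 0.2 * bx + pleio, sy)
    inst <- make_instruments(bx, by, sy)
    abs(mr_weighted_median(inst, n_boot = 2, seed = 1)$beta - 0.2) <
      abs(mr_ivw(inst)$beta - 0.2)
  })
  expect_gt(mean(wins), 0.8)
})

test_that("weighted mode finds the majority cluster", {
  inst <- make_instruments(rep(1, 10), rep(0.25, 10), rep(0.05, 10))
  expect_equal(mr_weighted_mode(inst, n_boot = 20, seed = 1)$beta, 0.25)
  inst2 <- make_instruments(rep(1, 10),
                            c(rep(0.2, 7), rep(0.8, 3)),
                            c(rep(0.05, 7), rep(0.08, 3)))
  est <- mr_weighted_mode(inst2, n_boot = 50, seed = 1)
  expect_lt(abs(est$beta - 0.2), 0.1)
  # bandwidth factor shifts smoothing but not the majority mode here
  est2 <- mr_weighted_mode(inst2, bandwidth_factor = 2, n_boot = 20,
                           seed = 1)
  expect_lt(abs(est2$beta - 0.2), 0.15)
})

test_that("all estimators are scale-equivariant in the exposure units", {
  set.seed(75)
  m <- 15
  bx <- runif(m, 0.1, 0.4)
  sy <- runif(m, 0.02, 0.08)
  by <- rnorm(m, 0.3 * bx, sy)
  sx <- rep(0.01, m)
  i1 <- make_instruments(bx, by, sy, sx)
  i2 <- make_instruments(2 * bx, by, sy, 2 * sx)
  expect_equal(mr_ivw(i2)$beta, mr_ivw(i1)$beta / 2, tolerance = 1e-12)
  expect_equal(mr_egger(i2)$slope$beta, mr_egger(i1)$slope$beta / 2,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(i2, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(i1, n_boot = 2, seed = 1)$beta / 2,
               tolerance = 1e-12)
})

test_that("estimators agree under valid instruments and no pleiotropy", {
  set.seed(76)
  ests <- replicate(100, {
    m <- 40
    bx <- runif(m, 0.1, 0.4)
    sy <- rep(0.03, m)
    by <- rnorm(m, 0.25 * bx, sy)
    inst <- make_instruments(bx, by, sy)
    c(mr_ivw(inst)$beta, mr_egger(inst)$slope$beta,
      mr_weighted_median(inst, n_boot = 2, seed = 1)$beta,
      mr_weighted_mode(inst, n_boot = 2, seed = 1)$beta)
  })
  means <- rowMeans(ests)
  expect_true(all(abs(means - 0.25) < 0.02))
})

test_that("hazard-ratio reporting converts scales correctly", {
  est <- mr_estimate("ivw", log(1.21), 0.034, 947)
  tab <- hr_per_sd(est, per_unit = TRUE)
  expect_equal(tab$hr[1], 1.21)
  expect_equal(tab$hr[2], 1.21^(1 / 4.8), tolerance = 1e-10)
  expect_equal(tab$hr[2], 1.0405, tolerance = 1e-4)
  null <- hr_per_sd(mr_estimate("ivw", 0, 0.1, 10))
  expect_equal(null$hr, 1)
  expect_lt(null$ci_low, 1)
  expect_gt(null$ci_high, 1)
})

test_that("the interaction Z-test matches the normal oracle", {
  a <- mr_estimate("ivw", 0.3, 0.1, 10)
  b <- mr_estimate("ivw", 0.3, 0.2, 10)
  z <- interaction_z(a, b)
  expect_equal(z$z, 0)
  expect_equal(z$p, 1)
  d <- 1.96 * sqrt(0.1^2 + 0.2^2)
  b2 <- mr_estimate("ivw", 0.3 - d, 0.2, 10)
  expect_equal(interaction_z(a, b2)$p, 0.05, tolerance = 1e-3)
  # direct normal-CDF oracle on a random fixture
  set.seed(77)
  for (i in 1:5) {
    e1 <- mr_estimate("ivw", rnorm(1), runif(1, 0.05, 0.3), 5)
    e2 <- mr_estimate("ivw", rnorm(1), runif(1, 0.05, 0.3), 5)
    zz <- (e1$beta - e2$beta) / sqrt(e1$se^2 + e2$se^2)
    expect_equal(interaction_z(e1, e2)$p, 2 * pnorm(-abs(zz)),
                 tolerance = 1e-12)
  }
  expect_error(interaction_z(mr_estimate("ivw", 0, 0, 1), a),
               "non-positive")
})

test_that("instrument-validity heterogeneity testing is Bonferroni-gated", {
  m <- 947
  set.seed(78)
  b <- rnorm(m, 0.1, 0.02)
  s1 <- make_stats(b, rep(0.01, m), pos = seq_len(m))
  s2 <- s1
  r <- instrument_validity_het(s1, s2)
  expect_true(r$valid)
  expect_equal(r$n_flagged, 0)
  expect_true(all(r$table$q == 0))
  expect_equal(r$threshold, 0.05 / 947, tolerance = 1e-12)
  expect_equal(r$threshold, 5.28e-5, tolerance = 1e-2)
  # one variant shifted by six pooled SEs is the only flag
  s3 <- s2
  s3$beta[100] <- s3$beta[100] + 6 * sqrt(2) * 0.01
  r3 <- instrument_validity_het(s1, s3)
  expect_false(r3$valid)
  expect_equal(r3$table$variant_id[r3$table$flagged], "v100")
  expect_error(instrument_validity_het(s1, make_stats(1, 1, ids = "zz")),
               "no shared")
})
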