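test_that("raw slope has exact closed-form behaviour", {
  inc <- make_stats(c(0.1, 0.2, -0.1, 0.3), rep(0.05, 4))
  # all-zero prognosis effects: slope 0
  prog0 <- make_stats(rep(0, 4), rep(0.08, 4))
  expect_equal(raw_slope(inc, prog0)$b, 0)
  # exact proportionality: slope recovered regardless of weights
  prog2 <- make_stats(2 * inc$beta, c(0.05, 0.2, 0.08, 0.11))
  expect_equal(raw_slope(inc, prog2)$b, 2, tolerance = 1e-12)
  expect_error(raw_slope(inc[1:2, ], prog2), "fewer than 3")
})

test_that("raw and CWLS slopes match a brute-force normal-equations oracle", {
  set.seed(60)
  m <- 50
  inc <- make_stats(rnorm(m, 0, 0.2), runif(m, 0.02, 0.1))
  prog <- make_stats(-0.3 * inc$beta + rnorm(m, 0, 0.05),
                     runif(m, 0.03, 0.12))
  w <- 1 / prog$se^2
  b_oracle <- sum(w * inc$beta * prog$beta) / sum(w * inc$beta^2)
  expect_equal(raw_slope(inc, prog)$b, b_oracle, tolerance = 1e-10)
  cf_oracle <- sum(w * inc$beta^2) /
    (sum(w * inc$beta^2) - sum(w * inc$se^2))
  cw <- cwls_adjust(inc, prog)
  expect_equal(cw$correction_factor, cf_oracle, tolerance = 1e-12)
  expect_equal(cw$b, cf_oracle * b_oracle, tolerance = 1e-12)
})

test_that("CWLS reduces to the raw slope without incidence measurement error", {
  set.seed(61)
  inc <- make_stats(rnorm(10, 0, 0.3), rep(1e-12, 10))
  prog <- make_stats(rnorm(10, 0, 0.1), rep(0.1, 10))
  expect_equal(cwls_adjust(inc, prog)$b, raw_slope(inc, prog)$b,
               tolerance = 1e-6)
  expect_equal(cwls_adjust(inc, prog)$correction_factor, 1,
               tolerance = 1e-6)
  # noise exceeding signal is rejected
  inc2 <- make_stats(rnorm(10, 0, 0.01), rep(0.5, 10))
  expect_error(cwls_adjust(inc2, prog), "too weak")
})

test_that("CWLS recovers a known slope through incidence measurement error", {
  set.seed(62)
  reps <- replicate(150, {
    m <- 80
    bI_true <- rnorm(m, 0, 0.2)
    seI <- rep(sqrt(0.5) * 0.2, m)  # noise variance half the signal variance
    bI <- rnorm(m, bI_true, seI)
    seP <- rep(0.05, m)
    bP <- rnorm(m, 1 * bI_true, seP)
    cwls_adjust(make_stats(bI, seI), make_stats(bP, seP))$b
  })
  expect_equal(mean(reps), 1, tolerance = 0.05)
})

test_that("Dudbridge adjustment equals CWLS under the default configuration", {
  set.seed(63)
  inc <- make_stats(rnorm(30, 0, 0.2), runif(30, 0.02, 0.08))
  prog <- make_stats(rnorm(30, 0, 0.1), runif(30, 0.04, 0.1))
  d <- dudbridge_adjust(inc, prog)
  cw <- cwls_adjust(inc, prog)
  expect_equal(d$b, cw$b)
  expect_equal(d$se_b, cw$se_b)
  expect_equal(d$adjusted$beta, cw$adjusted$beta)
  expect_equal(d$method, "dudbridge")
})

test_that("the affine correction is idempotent and propagates SEs", {
  set.seed(64)
  inc <- make_stats(rnorm(40, 0, 0.25), runif(40, 0.01, 0.03))
  prog <- make_stats(-0.4 * inc$beta + rnorm(40, 0, 0.05),
                     runif(40, 0.04, 0.08))
  adj <- cwls_adjust(inc, prog)
  expect_equal(adj$adjusted$beta, prog$beta - adj$b * inc$beta)
  expect_true(all(adj$adjusted$se >= prog$se))
  again <- cwls_adjust(inc, adj$adjusted)
  expect_lt(abs(again$b), 2 * again$se_b)
})

test_that("Slope-Hunter recovers cluster structure and exposes instability", {
  set.seed(65)
  m <- 200
  bI <- rnorm(m, 0, 0.2)
  # pure class 1: slope 1.5, tight noise
  prog1 <- make_stats(1.5 * bI + rnorm(m, 0, 0.02), rep(0.02, m))
  sh <- slope_hunter(make_stats(bI, rep(0.02, m)), prog1, n_starts = 5,
                     seed = 1)
  expect_equal(sh$b, 1.5, tolerance = 0.1)
  expect_gt(mean(sh$cluster_assignments > 0.9), 0.9)
  # 50/50 mixture with distinct slopes: class-1 slope recovered, pooled
  # WLS slope rejected
  bI2 <- rnorm(m, 0, 0.2)
  bP2 <- c(0.5 * bI2[1:100] + rnorm(100, 0, 0.02),
           2.0 * bI2[101:200] + rnorm(100, 0, 0.1))
  inc2 <- make_stats(bI2, rep(0.02, m))
  prog2 <- make_stats(bP2, rep(0.02, m))
  sh2 <- slope_hunter(inc2, prog2, n_starts = 10, seed = 2)
  pooled <- raw_slope(inc2, prog2)$b
  expect_lt(abs(sh2$b - 0.5), abs(sh2$b - pooled))
  # per-start slopes are reported so instability is observable
  expect_true(is.data.frame(sh2$per_start))
  expect_gte(nrow(sh2$per_start), 2)
  expect_error(slope_hunter(inc2[1:10, ], prog2[1:10, ]), "fewer than 20")
})

test_that("CWBLS collapses to IVW without incidence effects or measurement error", {
  set.seed(66)
  m <- 30
  bx <- rnorm(m, 0.2, 0.05)
  expo <- make_stats(bx, rep(1e-13, m))
  inc <- make_stats(rnorm(m, 0, 1e-13), rep(1e-13, m))
  sy <- runif(m, 0.03, 0.1)
  prog <- make_stats(0.5 * bx + rnorm(m, 0, 0.01), sy)
  expo$pvalue <- 1e-20  # all instruments
  inc$pvalue <- 1
  cw <- cwbls_bivariate(expo, inc, prog, variants = expo$variant_id)
  ivw <- sum(bx * prog$beta / sy^2) / sum(bx^2 / sy^2)
  expect_equal(cw$estimate$beta, ivw, tolerance = 1e-6)
})

test_that("CWBLS solves the error-free two-column system exactly", {
  # hand-computable: bP = 0.3 bx - 0.2 bI with no noise
  bx <- c(0.1, 0.2, 0.0, 0.0, 0.15)
  bI <- c(0.1, 0.2, 0.3, 0.1, 0.05)
  bP <- 0.3 * bx - 0.2 * bI
  expo <- make_stats(bx, rep(1e-13, 5))
  inc <- make_stats(bI, rep(1e-13, 5))
  prog <- make_stats(bP, rep(0.05, 5))
  cw <- cwbls_bivariate(expo, inc, prog,
                        variants = expo$variant_id)
  expect_equal(cw$estimate$beta, 0.3, tolerance = 1e-8)
  expect_equal(cw$adjustment$b, -0.2, tolerance = 1e-8)
  # singular corrected Gram matrix is rejected
  expo2 <- make_stats(bI, rep(0.3, 5))  # collinear and noise-dominated
  expect_error(cwbls_bivariate(expo2, make_stats(bI, rep(0.3, 5)), prog,
                               variants = expo2$variant_id),
               "too weak")
})

test_that("traditional MR slope uses incidence-significant instruments", {
  set.seed(67)
  m <- 40
  bI <- c(rnorm(10, 0.3, 0.02), rnorm(30, 0, 0.01))
  seI <- rep(0.01, m)
  prog <- make_stats(-0.5 * bI + rnorm(m, 0, 0.02), rep(0.03, m))
  inc <- make_stats(bI, seI)
  ms <- mr_slope_adjust(inc, prog)
  expect_equal(ms$b, -0.5, tolerance = 0.1)
  expect_equal(ms$method, "mr_slope")
  inc_weak <- make_stats(rnorm(m, 0, 0.001), rep(0.1, m))
  expect_error(mr_slope_adjust(inc_weak, prog), "fewer than 3")
})
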