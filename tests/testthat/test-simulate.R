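test_that("genotypes follow Hardy-Weinberg proportions and reject bad maf", {
  g <- simulate_genotypes(100000, 0.3, seed = 1)
  expect_true(all(g %in% 0:2))
  counts <- tabulate(g + 1L, 3)
  chisq <- sum((counts - 1e5 * c(0.49, 0.42, 0.09))^2 /
                 (1e5 * c(0.49, 0.42, 0.09)))
  expect_lt(chisq, qchisq(0.999, df = 2))
  # column mean within 4 SE of 2*maf at maf = 0.5
  g5 <- simulate_genotypes(100000, 0.5, seed = 2)
  expect_lt(abs(mean(g5) - 1), 4 * sqrt(0.5 / 1e5))
  # rare variant: mostly zeros, all in range
  gr <- simulate_genotypes(100, 1e-4, seed = 3)
  expect_true(all(gr %in% 0:2))
  expect_gt(mean(gr == 0), 0.9)
  expect_error(simulate_genotypes(100, c(0.3, 0.7), seed = 1),
               "offending index: 2")
  expect_error(simulate_genotypes(100, c(NA, 0.1)), "offending index: 1")
})

test_that("exposure is standardized with tracked effects and variance partition", {
  g <- simulate_genotypes(100000, rep(0.3, 5), seed = 4)
  # null effects: standard normal, uncorrelated with variants
  e0 <- simulate_exposure(g, rep(0, 5), env_sd = 1, seed = 5)
  expect_equal(mean(e0), 0, tolerance = 1e-12)
  expect_equal(sd(e0), 1, tolerance = 1e-12)
  expect_lt(max(abs(cor(e0, g))), 0.02)
  # single variant, no noise: exactly 3 distinct values
  e1 <- simulate_exposure(g[, 1, drop = FALSE], 1, env_sd = 0, seed = 6)
  expect_equal(length(unique(round(e1, 10))), 3)
  # degenerate rejected
  expect_error(simulate_exposure(g, rep(0, 5), env_sd = 0, seed = 1),
               "degenerate")
  # variance partition: effects sized for 25% explained
  m <- 100
  maf <- rep(0.3, m)
  gg <- simulate_genotypes(100000, maf, seed = 7)
  eff <- rep(sqrt(0.25 / m / (2 * 0.3 * 0.7)), m)
  ee <- simulate_exposure(gg, eff, env_sd = sqrt(0.75), seed = 8)
  score <- gg %*% eff
  r2 <- summary(lm(ee ~ score))$r.squared
  expect_gt(r2, 0.22)
  expect_lt(r2, 0.28)
  # tracked standardized effects match the construction
  expect_equal(attr(ee, "effects_std"), eff / attr(ee, "sd_raw"))
})

test_that("onset is a collider: pre-selection independence, case-only negative correlation", {
  n <- 200000
  set.seed(9)
  e <- rnorm(n)
  u <- rnorm(n)
  expect_lt(abs(cor(e, u)), 0.02)
  # null coefficients: onset rate ~ 0.5
  on0 <- simulate_onset(e, u, 0, 0, 0, seed = 10)
  expect_lt(abs(mean(on0) - 0.5), 4 * sqrt(0.25 / n))
  # collider signature
  on <- simulate_onset(e, u, -3, 1, 1, seed = 11)
  expect_lt(cor(e[on == 1], u[on == 1]), -0.05)
  # intercept -50: no onsets, downstream raises empty case set
  none <- simulate_onset(e[1:1000], u[1:1000], -50, 1, 1, seed = 12)
  expect_equal(sum(none), 0)
  expect_error(simulate_prognosis(numeric(0), numeric(0), 0, 0, 0.1, 0, 10),
               "empty case set")
})

test_that("prognosis times are exponential with proportional hazards", {
  n <- 50000
  e <- rnorm(n)
  u <- rnorm(n)
  # null effects: mean time ~ 1/rate
  pr <- simulate_prognosis(e, u, 0, 0, 0.05, 0, Inf, seed = 13)
  expect_true(all(pr$time > 0))
  expect_lt(abs(mean(pr$time) - 20), 4 * 20 / sqrt(n))
  expect_true(all(pr$event == "primary"))
  # Cox recovers log(1.2) on a large case set
  pr2 <- simulate_prognosis(e, u, log(1.2), 0, 0.05, 0, 20, seed = 14)
  fit <- cox_fit(pr2$time, as.integer(pr2$event == "primary"),
                 cbind(exposure = e))
  expect_equal(unname(fit$coefficients), log(1.2), tolerance = 0.02)
  # near-zero censor horizon: everything censored
  pr3 <- simulate_prognosis(e[1:100], u[1:100], 0, 0, 0.05, 0, 1e-9,
                            seed = 15)
  expect_true(all(pr3$event == "censored"))
  # impossible configuration rejected
  expect_error(simulate_prognosis(e, u, 0, 0, 0, 0, Inf), "no events")
})

test_that("simulate_cohort is deterministic and serializes byte-identically", {
  cfg <- simulation_config(n_individuals = 500, n_variants = 30, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_cohort(a, f1)
  write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves the data
  back <- read_cohort(f1)
  expect_equal(back$exposure, a$exposure)
  expect_equal(unname(attr(back, "genotypes")), unname(attr(a, "genotypes")))
  # adding variants does not perturb the survival draws (per-stage streams)
  cfg2 <- simulation_config(n_individuals = 500, n_variants = 60, seed = 77)
  c2 <- simulate_cohort(cfg2)
  expect_equal(c2$competitor, a$competitor)
  expect_equal(c2$age, a$age)
})

test_that("cohort invariants hold: time defined only for cases, dosages integral", {
  co <- small_cohort(seed = 3)
  expect_true(all(is.na(co$time[co$onset == 0])))
  expect_true(all(co$time[co$onset == 1] > 0))
  g <- attr(co, "genotypes")
  expect_true(all(g %in% 0:2))
  expect_lt(abs(cor(co$exposure, co$competitor)), 0.05)
})

test_that("summary statistics flag monomorphic variants and calibrate under the null", {
  co <- small_cohort(seed = 5, n = 3000, m = 60)
  g <- attr(co, "genotypes")
  g[, 60] <- 0L  # force monomorphic
  attr(co, "genotypes") <- g
  for (which in c("incidence", "prognosis", "exposure")) {
    st <- build_summary_stats(co, which)
    expect_false(st$estimable[60])
    expect_equal(st$beta[60], 0)
    expect_true(all(st$estimable[1:59]))
  }
  # per-variant prognosis z^2 equals the cox_fit Wald statistic
  prog <- per_variant_cox(co, variants = 7)
  cases <- co[co$onset == 1, ]
  f <- cox_fit(cases$time, as.integer(cases$event == "primary"),
               cbind(g = g[co$onset == 1, 7], age = cases$age,
                     sex = cases$sex))
  expect_equal((prog$beta / prog$se)^2,
               unname((f$coefficients["g"] / f$se["g"])^2),
               tolerance = 1e-8)
  # empty case set rejected
  co$onset[] <- 0L
  expect_error(build_summary_stats(co, "prognosis"), "empty case set")
})
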