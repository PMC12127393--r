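# effects with SE = 0.1, 0.2, 0.4 are encoded as n = 3 + 1/SE^2
fit_from_z <- function(zi, sei, method = "FE") {
  meta_pool(tanh(zi), 3 + 1 / sei^2, method = method)
}

test_that("Egger regression matches the closed-form OLS oracle and frozen fixture", {
  fit <- fit_from_z(c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.4))
  eg <- egger_test(fit)
  expect_equal(eg$intercept, 0.75, tolerance = 1e-10)
  expect_equal(eg$slope, 0.12857143, tolerance = 1e-7)
  expect_equal(eg$df, 1L)
  orc <- oracle_egger(c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.4))
  expect_equal(eg$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(eg$se_intercept, orc$se_intercept, tolerance = 1e-10)
  expect_equal(eg$t_stat, orc$t, tolerance = 1e-10)
  expect_equal(eg$pval, orc$p, tolerance = 1e-10)
})

test_that("Egger regression agrees with the oracle on random small fixtures", {
  set.seed(8)
  for (i in 1:10) {
    k <- sample(4:6, 1)
    sei <- runif(k, 0.05, 0.4)
    zi <- rnorm(k, 0.2, 0.1)
    eg <- egger_test(fit_from_z(zi, sei))
    orc <- oracle_egger(zi, sei)
    expect_equal(eg$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(eg$slope, orc$slope, tolerance = 1e-10)
    expect_equal(eg$pval, orc$p, tolerance = 1e-10)
  }
})

test_that("standardized effects exactly proportional to precision give a zero intercept", {
  sei <- c(0.1, 0.15, 0.25, 0.4)
  eg <- suppressWarnings(egger_test(fit_from_z(rep(0.3, 4), sei)))
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$slope, 0.3, tolerance = 1e-10)
})

test_that("Egger preconditions: k >= 3 and non-degenerate precision design", {
  expect_error(egger_test(fit_from_z(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
  expect_error(egger_test(fit_from_z(c(0.1, 0.2, 0.3), rep(0.1, 3))),
               "identical")
})

test_that("fail-safe N reproduces the Rosenthal closed form and the 5k+10 criterion", {
  # three studies each scoring Z = 3: N = ceil(81/1.96^2 - 3) = 19
  fit <- fit_from_z(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))
  fs <- fail_safe_n(fit)
  expect_equal(fs$n_fs, 19L)
  expect_equal(fs$criterion_5k_10, 25L)
  expect_false(fs$robust)

  null_fit <- fit_from_z(c(0.01, -0.01, 0.02), rep(0.1, 3))
  expect_equal(fail_safe_n(null_fit)$n_fs, 0L)

  k48 <- meta_pool(rep(-0.2, 48) + seq(-0.05, 0.05, length.out = 48),
                   rep(500, 48))
  expect_equal(fail_safe_n(k48)$criterion_5k_10, 250L)
  k10 <- meta_pool(rep(0.21, 10) + seq(-0.02, 0.02, length.out = 10),
                   rep(400, 10))
  expect_equal(fail_safe_n(k10)$criterion_5k_10, 60L)
})

test_that("fail-safe N satisfies its defining inequality on randomized fixtures", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(3:20, 1)
    zi <- rnorm(k, 0.25, 0.1)
    sei <- runif(k, 0.05, 0.3)
    fs <- fail_safe_n(fit_from_z(zi, sei))
    S <- sum(zi / sei)
    expect_lt(abs(S) / sqrt(k + fs$n_fs), fs$z_crit)
    if (fs$n_fs >= 1)
      expect_gte(abs(S) / sqrt(k + fs$n_fs - 1), fs$z_crit)
  }
})

test_that("one-tailed fail-safe uses z_crit = 1.645", {
  fit <- fit_from_z(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))
  fs1 <- fail_safe_n(fit, sides = 1)
  expect_equal(fs1$z_crit, qnorm(0.95), tolerance = 1e-12)
  expect_gt(fs1$n_fs, fail_safe_n(fit)$n_fs)
})

test_that("trim-and-fill reproduces the hand-computed L0 iteration fixture", {
  fit <- fit_from_z(c(0, 0.55, 0.6, 0.65, 0.7), rep(0.1, 5), method = "DL")
  tf <- trim_and_fill(fit, side = "right")
  expect_equal(tf$l0, 1L)
  expect_equal(tf$imputed$z, 0.2, tolerance = 1e-10)
  expect_equal(tf$center_z, 0.45, tolerance = 1e-10)
  expect_equal(tf$adjusted$b, 0.45, tolerance = 1e-10)
  expect_gte(tf$iterations, 1L)
  # auto side detection picks the same heavy side
  expect_equal(trim_and_fill(fit)$side, "right")
})

test_that("trim-and-fill is the identity on symmetric data", {
  fit <- fit_from_z(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.1, 5), method = "DL")
  tf <- trim_and_fill(fit)
  expect_equal(tf$l0, 0L)
  expect_equal(tf$adjusted$b, fit$b, tolerance = 1e-12)
  expect_equal(tf$adjusted$r, fit$r, tolerance = 1e-12)
  expect_equal(nrow(tf$imputed), 0L)
})

test_that("imputed studies are exact mirror images with preserved variances", {
  # right-heavy cluster with unequal precisions
  zi <- c(0, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75)
  sei <- c(0.1, 0.12, 0.1, 0.11, 0.1, 0.13, 0.09)
  fit <- fit_from_z(zi, sei)
  tf <- trim_and_fill(fit, side = "right")
  expect_gt(tf$l0, 0L)
  trimmed <- sort(zi, decreasing = TRUE)[seq_len(tf$l0)]
  expect_equal(sort(tf$imputed$z), sort(2 * tf$center_z - trimmed),
               tolerance = 1e-10)
  trim_idx <- order(zi, decreasing = TRUE)[seq_len(tf$l0)]
  expect_equal(sort(tf$imputed$vi), sort(sei[trim_idx]^2), tolerance = 1e-8)
})

test_that("a funnel heavy near zero imputes on the far side, strengthening the pooled effect", {
  # negative-effect literature over-representing weak results: the heavy
  # side is the near-zero (right) side, imputation pushes the summary more
  # negative
  fit <- fit_from_z(c(-0.45, -0.2, -0.18, -0.15, -0.12), rep(0.1, 5),
                    method = "DL")
  tf <- trim_and_fill(fit)
  expect_equal(tf$side, "right")
  expect_equal(tf$l0, 1L)
  expect_equal(tf$imputed$z, -0.37, tolerance = 1e-10)
  expect_lt(tf$adjusted$r, fit$r)
})

test_that("the L0 estimator agrees with metafor on random data for both trimming sides", {
  skip_if_not_installed("metafor")
  # metafor labels the imputation side; this package labels the trimmed
  # (heavy) side - so "right" here pairs with metafor's "left", and vice
  # versa. Sides are fixed explicitly because the two packages use different
  # auto-detection heuristics (one-sided rank sums here, regression there).
  set.seed(37)
  for (i in 1:6) {
    k <- sample(8:20, 1)
    zi <- rnorm(k, 0.2, 0.15) + c(rep(0.3, 3), rep(0, k - 3))
    ni <- sample(30:800, k)
    fit <- meta_pool(tanh(zi), ni, method = "FE")
    ref <- metafor::rma(yi = zi, vi = 1 / (ni - 3), method = "FE")
    expect_equal(trim_and_fill(fit, side = "right")$l0,
                 as.integer(suppressWarnings(
                   metafor::trimfill(ref, side = "left"))$k0))
    expect_equal(trim_and_fill(fit, side = "left")$l0,
                 as.integer(suppressWarnings(
                   metafor::trimfill(ref, side = "right"))$k0))
  }
})

test_that("funnel coordinates expose observed and imputed points around the pooled center", {
  fit <- fit_from_z(c(0, 0.55, 0.6, 0.65, 0.7), rep(0.1, 5), method = "DL")
  fc <- funnel_coordinates(fit)
  expect_equal(nrow(fc$points), 5L)
  expect_equal(fc$points$sei, rep(0.1, 5), tolerance = 1e-10)
  expect_equal(fc$center, fit$b)

  sym <- fit_from_z(c(-0.2, -0.1, 0.1, 0.2), rep(0.1, 4), method = "FE")
  fcs <- funnel_coordinates(sym)
  expect_equal(sum(fcs$points$z > fcs$center), sum(fcs$points$z < fcs$center))

  tf <- trim_and_fill(fit, side = "right")
  fct <- funnel_coordinates(fit, tf)
  expect_equal(sum(fct$points$source == "imputed"), tf$l0)
})
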