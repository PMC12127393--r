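table4 <- function() {
  pooled_matrix(c(pa_mpa = -0.184, pa_sc = 0.213, sc_mpa = -0.449),
                n_effective = 11386)
}

test_that("the pooled-matrix container validates symmetry, diagonal and definiteness", {
  m <- table4()
  expect_equal(m$r["PA", "SC"], 0.213)
  expect_equal(m$r, t(m$r))
  bad <- diag(3); bad[1, 2] <- 0.5  # asymmetric
  expect_error(pooled_matrix(bad, 100), "symmetric")
  npd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(pooled_matrix(npd, 100), "positive definite")
  expect_error(pooled_matrix(c(pa_mpa = -0.1, pa_sc = 1, sc_mpa = -0.4), 100),
               "inside")
})

test_that("pooled matrices round-trip through the JSON fixture format", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- table4()
  m$cell_k <- c(pa_mpa = 48L, pa_sc = 10L, sc_mpa = 10L)
  write_pooled_matrix(m, path)
  back <- read_pooled_matrix(path)
  expect_equal(back$r, m$r, tolerance = 1e-12)
  expect_equal(back$n_effective, 11386)
  expect_equal(unname(back$cell_k), c(48L, 10L, 10L))
  bundled <- read_pooled_matrix(
    system.file("extdata", "pooled_pa_sc_mpa.json", package = "masemcor"))
  expect_equal(bundled$r, m$r, tolerance = 1e-12)
})

test_that("the saturated mediation fit reproduces the published decomposition", {
  fit <- stage2_fit_mediation(table4())
  co <- coef(fit)
  expect_equal(unname(co["a"]), 0.213, tolerance = 1e-12)
  expect_lte(abs(co[["b"]] - (-0.429)), 0.002)
  expect_lte(abs(co[["ab"]] - (-0.091)), 0.002)
  expect_lte(abs(co[["c"]] - (-0.092)), 0.002)
  expect_equal(unname(co["d"]), -0.184, tolerance = 1e-12)
  expect_lte(abs(fit$prop_mediated$value - 0.497), 0.005)
  expect_equal(fit$fit$df, 0L)
  expect_lte(fit$fit$chi2, 1e-8)
  expect_equal(fit$fit$cfi, 1)
  expect_equal(fit$fit$tli, 1)
  expect_equal(fit$fit$rmsea, 0)
})

test_that("degenerate path structures solve exactly", {
  # no PA-SC association: no mediation pathway
  m0 <- pooled_matrix(c(pa_mpa = -0.3, pa_sc = 0, sc_mpa = -0.4), 1000)
  f0 <- stage2_fit_mediation(m0)
  expect_equal(unname(coef(f0)["a"]), 0)
  expect_equal(unname(coef(f0)["ab"]), 0)
  expect_equal(unname(coef(f0)["c"]), -0.3, tolerance = 1e-12)

  # r(PA,MPA) = r(PA,SC) * r(SC,MPA): full mediation, c = 0
  mfull <- pooled_matrix(c(pa_mpa = 0.3 * -0.5, pa_sc = 0.3, sc_mpa = -0.5),
                         1000)
  ffull <- stage2_fit_mediation(mfull)
  expect_equal(unname(coef(ffull)["c"]), 0, tolerance = 1e-12)
  expect_equal(unname(coef(ffull)["ab"]), unname(coef(ffull)["d"]),
               tolerance = 1e-12)
  orc <- oracle_stage2(mfull$r)
  expect_equal(unname(coef(ffull)[c("a", "b", "c")]), unname(orc),
               tolerance = 1e-6)
})

test_that("stage-2 estimates match the brute-force discrepancy minimizer on random matrices", {
  set.seed(47)
  for (i in 1:50) {
    R <- random_pd_corr3()
    fit <- stage2_fit_mediation(R, n_effective = 5000)
    orc <- oracle_stage2(fit$R)
    expect_equal(unname(coef(fit)[c("a", "b", "c")]), unname(orc),
                 tolerance = 1e-6)
    # saturated model reproduces its input matrix
    expect_equal(fit$implied, fit$R, tolerance = 1e-10)
    # decomposition identity: total effect equals the simple regression
    # coefficient of MPA on PA, i.e. r(PA, MPA)
    expect_equal(unname(coef(fit)["d"]), fit$R["PA", "MPA"], tolerance = 1e-12)
    expect_equal(unname(coef(fit)["c"] + coef(fit)["ab"]),
                 unname(coef(fit)["d"]), tolerance = 1e-12)
  }
})

test_that("collinear or near-unit predictor correlations are rejected", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 1 - 1e-13
  # caught at the matrix boundary: correlations this close to 1 are refused
  expect_error(stage2_fit_mediation(R, n_effective = 100),
               "inside \\(-1, 1\\)|collinear")
})

test_that("proportion mediated handles full, null and inconsistent mediation", {
  fit <- stage2_fit_mediation(table4())
  pm <- proportion_mediated(fit)
  expect_true(pm$defined)
  expect_lte(abs(pm$value - 0.497), 0.005)
  expect_equal(proportion_mediated(0, -0.2)$value, 0)
  expect_equal(proportion_mediated(-0.2, -0.2)$value, 1)
  inc <- proportion_mediated(0.05, -0.1)
  expect_false(inc$defined)
  expect_true(is.na(inc$value))
  expect_equal(inc$code, "inconsistent_mediation")
  # full mediation via the model: c = 0
  mfull <- pooled_matrix(c(pa_mpa = -0.15, pa_sc = 0.3, sc_mpa = -0.5), 1000)
  expect_equal(proportion_mediated(stage2_fit_mediation(mfull))$value, 1,
               tolerance = 1e-10)
})

test_that("Monte-Carlo intervals for the indirect effect behave and converge", {
  fit <- stage2_fit_mediation(table4())
  ci <- indirect_ci_montecarlo(fit, seed = 99)
  ab <- coef(fit)[["ab"]]
  expect_lt(ci[["lower"]], ab)
  expect_gt(ci[["upper"]], ab)
  expect_gt(ci[["lower"]], -0.15)
  expect_lt(ci[["upper"]], -0.04)
  # reproducible under the same seed
  expect_equal(ci, indirect_ci_montecarlo(fit, seed = 99))
  # doubling the draws moves the endpoints by < 0.002 at this n
  ci2 <- indirect_ci_montecarlo(fit, draws = 20000L, seed = 123)
  expect_lt(max(abs(ci2 - ci)), 0.002)
  # degenerate SEs collapse the interval onto the point estimate
  fit0 <- fit
  fit0$se[c("a", "b")] <- 0
  ci0 <- indirect_ci_montecarlo(fit0, seed = 1)
  expect_equal(unname(ci0), c(ab, ab), tolerance = 1e-12)
  expect_error(indirect_ci_montecarlo(fit, draws = 10), "1000")
})

test_that("stage 1 pools each cell over its reporting studies with honest bookkeeping", {
  # identical complete studies pool to their common matrix exactly
  tab <- data.frame(study_id = paste0("s", 1:4), n = rep(500L, 4),
                    r_pa_mpa = rep(-0.2, 4), r_pa_sc = rep(0.25, 4),
                    r_sc_mpa = rep(-0.45, 4), stringsAsFactors = FALSE)
  m <- stage1_pool_matrix(tab)
  expect_equal(m$r["PA", "MPA"], -0.2, tolerance = 1e-12)
  expect_equal(m$r["PA", "SC"], 0.25, tolerance = 1e-12)
  expect_equal(m$r["SC", "MPA"], -0.45, tolerance = 1e-12)
  expect_equal(m$n_effective, 2000L)

  # mixed missingness: 38 partial + 10 complete studies
  st <- simulate_studies(sim_config(), seed = 77)
  m2 <- stage1_pool_matrix(st)
  expect_equal(unname(m2$cell_k), c(48L, 10L, 10L))
  expect_equal(m2$n_effective,
               sum(st$n[!is.na(st$r_pa_sc)]))
  # harmonic rule: harmonic mean of complete studies times their count
  nc <- st$n[!is.na(st$r_pa_sc)]
  m3 <- stage1_pool_matrix(st, n_rule = "harmonic")
  expect_equal(m3$n_effective, round(length(nc)^2 / sum(1 / nc)))
  # explicit override wins
  expect_equal(stage1_pool_matrix(st, n_effective = 11386)$n_effective, 11386)

  # a cell with fewer than 2 studies is an error
  tab1 <- tab
  tab1$r_pa_sc[2:4] <- NA
  tab1$r_sc_mpa[2:4] <- NA
  expect_error(stage1_pool_matrix(tab1), "at least 2")
})

test_that("stage 1 recovers a known population matrix without heterogeneity", {
  cfg <- sim_config(tau_z = 0, k_total = 10, k_complete = 10,
                    n_range = c(900, 1100), prop_secondary = 0,
                    moderator_shift = 0)
  set.seed(101)
  st <- simulate_studies(cfg, seed = 101)
  m <- stage1_pool_matrix(st)
  pop <- cfg$population_matrix
  for (pair in list(c("PA", "MPA"), c("PA", "SC"), c("SC", "MPA"))) {
    mc_se <- sqrt(1 / (10 * 997))  # pooled z SE at tau = 0
    err <- abs(atanh(m$r[pair[1], pair[2]]) - atanh(pop[pair[1], pair[2]]))
    expect_lt(err, 3 * mc_se)
  }
})

test_that("simulated paths are recovered end to end through both stages", {
  set.seed(211)
  reps <- 200
  truth <- c(a = 0.2, b = -0.45, c = -0.1)
  cfg <- sim_config(paths = truth, tau_z = 0.02, k_total = 10,
                    k_complete = 10, n_range = c(800, 1250),
                    prop_secondary = 0, moderator_shift = 0)
  ok <- logical(reps)
  for (i in seq_len(reps)) {
    st <- simulate_studies(cfg)
    fit <- stage2_fit_mediation(stage1_pool_matrix(st))
    ok[i] <- all(abs(coef(fit)[c("a", "b", "c")] - truth) <= 0.05)
  }
  expect_gte(mean(ok), 0.95)
})
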