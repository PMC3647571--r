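# System GMM estimator: differencing, instrument construction, estimation
# and diagnostics.

test_that("first differences form only across consecutive observations", {
  p <- toy_panel()
  d <- first_difference(p, "y")
  # patient 1: 7.0, 6.5, 6.5 at t = 1,2,3
  expect_equal(d$dy[d$patient_id == 1], c(-0.5, 0.0))
  # patient 2 has a gap at t = 2: no difference across it
  expect_identical(sum(d$patient_id == 2), 0L)
  # patient 3 has a single observation: empty differenced series
  expect_identical(sum(d$patient_id == 3), 0L)
})

test_that("uncollapsed instrument count matches a brute-force enumeration", {
  set.seed(1)
  n <- 40; T <- 3
  panel <- gen_ar1_panel(n = n, T = T)
  spec <- model_spec("y", predetermined = "x", collapse = FALSE)
  d <- build_instruments(panel, spec)
  # enumeration oracle over (t, lag) pairs:
  # differenced equation, t = 2..T:  y lags 2..t  and x lags 1..t (x_0 exists)
  n_diff <- 0
  for (t in 2:T) n_diff <- n_diff + length(2:t) + length(1:t)
  # levels equation: collapsed-by-construction IV columns do not vary by t;
  # GMM-style columns are per period: Dy_{t-1} for t = 2..T, Dx_t for t = 1..T
  n_lvl_gmm <- length(2:T) + T
  # IV columns: constant in levels (x is predetermined here, no exogenous
  # regressors, and time-invariant differences drop out)
  n_iv <- 1
  expect_identical(ncol(d$Z), as.integer(n_diff + n_lvl_gmm + n_iv))
  # every period-specific column is nonzero only in its own period
  percol <- d$cols[!is.na(d$cols$period), ]
  for (i in seq_len(nrow(percol))) {
    key <- rownames(percol)[i]
    nz <- d$Z[, key] != 0
    expect_true(all(d$rows$t[nz] == percol$period[i]))
  }
})

test_that("collapsing strictly reduces the instrument count for T >= 4", {
  set.seed(2)
  panel <- gen_ar1_panel(n = 60, T = 5)
  unc <- build_instruments(panel, model_spec("y", predetermined = "x",
                                             collapse = FALSE))
  col <- build_instruments(panel, model_spec("y", predetermined = "x",
                                             collapse = TRUE))
  expect_lt(ncol(col$Z), ncol(unc$Z))
})

test_that("endogenous regressors are instrumented from lag 2, not lag 1", {
  set.seed(3)
  panel <- gen_ar1_panel(n = 60, T = 5)
  d_endo <- build_instruments(panel, model_spec("y", endogenous = "x"))
  lags <- d_endo$cols$lag[d_endo$cols$variable == "x" &
                            d_endo$cols$part == "diff"]
  expect_true(all(lags >= 2))
  d_pre <- build_instruments(panel, model_spec("y", predetermined = "x"))
  lags_pre <- d_pre$cols$lag[d_pre$cols$variable == "x" &
                               d_pre$cols$part == "diff"]
  expect_identical(min(lags_pre), 1L)
})

test_that("panels that are too short for estimation raise a clear error", {
  p <- data.frame(patient_id = rep(1:5, each = 2), duration = rep(0:1, 5),
                  y = rnorm(10), x = rnorm(10))
  expect_error(build_instruments(p, model_spec("y", exogenous = "x")),
               "at least 3 periods")
})

test_that("two-step system GMM recovers the lag coefficient on synthetic data", {
  set.seed(42)
  panel <- gen_ar1_panel(n = 800, T = 7, alpha = 0.5, beta = 0.3)
  fit <- dpm_gmm(panel, model_spec("y", predetermined = "x", max_lag = 4))
  expect_equal(coef(fit)[["lag_y"]], 0.5, tolerance = 0.05)
  expect_equal(coef(fit)[["x"]], 0.3, tolerance = 0.05)
  expect_true(all(fit$se > 0))
  # fit bookkeeping
  expect_identical(fit$n_patients, 800L)
  expect_identical(fit$person_years, 800L * 7L)
  expect_gt(fit$n_instruments, fit$n_parameters)
})

test_that("without patient heterogeneity GMM agrees with pooled least squares", {
  set.seed(7)
  panel <- gen_ar1_panel(n = 1500, T = 6, alpha = 0.5, sigma_mu = 0)
  spec <- model_spec("y", exogenous = "x", max_lag = 4)
  fit <- dpm_gmm(panel, spec)
  ols <- pooled_ols(panel, spec)
  # with sigma_mu = 0 pooled OLS is consistent; both estimators should land
  # on the truth within sampling error
  expect_lt(abs(coef(fit)[["lag_y"]] - ols$coefficients[["lag_y"]]), 0.04)
  expect_lt(abs(ols$coefficients[["lag_y"]] - 0.5), 0.03)
})

test_that("estimates are invariant to patient order and id relabeling", {
  set.seed(8)
  panel <- gen_ar1_panel(n = 120, T = 5)
  spec <- model_spec("y", predetermined = "x", max_lag = 3)
  f1 <- dpm_gmm(panel, spec)
  shuffled <- panel[sample(nrow(panel)), ]
  f2 <- dpm_gmm(shuffled, spec)
  relabeled <- panel
  relabeled$patient_id <- 7 * relabeled$patient_id + 1000
  f3 <- dpm_gmm(relabeled, spec)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(coef(f1), coef(f3), tolerance = 1e-8)
})

test_that("collapsed and uncollapsed estimates agree on large panels", {
  set.seed(9)
  panel <- gen_ar1_panel(n = 2000, T = 5)
  a_col <- coef(dpm_gmm(panel, model_spec("y", predetermined = "x",
                                          collapse = TRUE)))[["lag_y"]]
  a_unc <- coef(dpm_gmm(panel, model_spec("y", predetermined = "x",
                                          collapse = FALSE)))[["lag_y"]]
  expect_equal(a_col, a_unc, tolerance = 0.03)
})

test_that("gaps break differencing but deeper-lag instruments survive", {
  set.seed(10)
  panel <- gen_ar1_panel(n = 400, T = 7)
  # knock out one mid-panel year for half the patients
  drop <- panel$duration == 3 & panel$patient_id <= 200
  fit <- dpm_gmm(panel[!drop, ], model_spec("y", predetermined = "x",
                                            max_lag = 4))
  expect_equal(coef(fit)[["lag_y"]], 0.5, tolerance = 0.07)
})

test_that("degenerate diagnostic cases are signalled explicitly", {
  set.seed(11)
  panel <- gen_ar1_panel(n = 200, T = 3)
  # max_lag 2 with T = 3 leaves few instruments; force just-identification
  # by an artificial spec: dep-var lags only, collapsed
  d <- build_instruments(panel, model_spec("y", max_lag = 2))
  fit <- dpm_gmm(panel, model_spec("y", max_lag = 2))
  if (fit$n_instruments == fit$n_parameters)
    expect_error(hansen_test(fit), "just-identified")
  else
    expect_s3_class(data.frame(p = hansen_test(fit)$p.value), "data.frame")
  # order-2 test impossible with only one usable differenced period
  fit3 <- dpm_gmm(gen_ar1_panel(n = 200, T = 3), model_spec("y"))
  expect_error(ar_test(fit3, 2), "AR\\(2\\) test undefined")
  expect_error(dpm_gmm(panel[panel$duration < 2, ], model_spec("y")),
               "at least 3 periods|estimation impossible")
})

test_that("under-identification and instrument collinearity are reported", {
  set.seed(12)
  panel <- gen_ar1_panel(n = 100, T = 3)
  # a time-invariant endogenous regressor with lag depth 1 contributes a
  # parameter but no usable instrument
  panel$z <- rnorm(100)[panel$patient_id]
  expect_error(dpm_gmm(panel, model_spec("y", endogenous = "z", max_lag = 1)),
               "under-identified")
  # exactly collinear regressors make the GMM normal equations singular
  panel$x2 <- rnorm(nrow(panel))
  panel$x3 <- panel$x + 2 * panel$x2
  expect_error(dpm_gmm(panel, model_spec("y", exogenous = c("x", "x2", "x3"))),
               "singular|collinear")
})
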