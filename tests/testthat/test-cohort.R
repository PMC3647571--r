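# Synthetic cohort generator: determinism, the noise-free limit, register
# moments, inclusion criteria and yearly averaging.

test_that("the same seed reproduces the panel exactly", {
  p1 <- generate_cohort(cohort_params(n = 80, seed = 123))
  p2 <- generate_cohort(cohort_params(n = 80, seed = 123))
  expect_identical(p1, p2)
  p3 <- generate_cohort(cohort_params(n = 80, seed = 124))
  expect_false(identical(p1, p3))
})

test_that("generated panels satisfy the panel invariants by construction", {
  panel <- generate_cohort(cohort_params(n = 150, seed = 5))
  expect_false(anyDuplicated(paste(panel$patient_id, panel$duration)) > 0)
  expect_true(all(panel$duration == round(panel$duration)))
  expect_true(all(panel$duration >= 0))
  expect_identical(panel$duration,
                   panel$calendar_year - panel$year_of_diagnosis)
  # unbalanced follow-up: staggered diagnosis years and dropout
  len <- tapply(panel$duration, panel$patient_id, max)
  expect_gt(length(unique(len)), 1)
})

test_that("the noise-free limit reproduces the deterministic engine", {
  pars <- cohort_params(n = 6, seed = 99,
                        sigma_mu = setNames(rep(0, 5), risk_factors()),
                        sigma_nu = setNames(rep(0, 5), risk_factors()),
                        dropout = 0, missingness = 0,
                        smoking_persistence = c(smoker = 1, nonsmoker = 1))
  panel <- generate_cohort(pars)
  for (id in unique(panel$patient_id)) {
    pp <- panel[panel$patient_id == id, ]
    pp <- pp[order(pp$duration), ]
    b <- pp[1, ]
    prof <- patient_profile(b$age_at_diagnosis, b$female, b$smoking,
                            hba1c = b$hba1c, sbp = b$sbp, bmi = b$bmi,
                            tchdl = b$tchdl, ldl = b$ldl)
    tr <- simulate_path(prof, horizon = max(pp$duration), level = "none")
    for (rf in risk_factors())
      expect_equal(pp[[rf]], unname(tr$values[rf, ]), tolerance = 1e-10)
  }
})

test_that("baseline moments match the register table within Monte Carlo error", {
  panel <- generate_cohort(cohort_params(n = 5043, seed = 2026))
  b <- panel[panel$duration == 0, ]
  m <- b[b$female == 0, ]; f <- b[b$female == 1, ]
  expect_equal(mean(m$hba1c), 7.0, tolerance = 0.08)
  expect_equal(mean(f$hba1c), 6.9, tolerance = 0.08)
  expect_equal(mean(m$bmi), 29.8, tolerance = 0.25)
  expect_equal(mean(m$sbp), 138.5, tolerance = 0.9)
  expect_equal(sd(m$hba1c), 1.4, tolerance = 0.12)
  expect_equal(mean(b$female), 2076 / 5043, tolerance = 0.03)
  expect_equal(mean(m$smoking), 0.21, tolerance = 0.03)
  # variance-stationarity: cross-sectional SD at year 3 stays near the
  # baseline SD
  y3 <- panel[panel$duration == 3, ]
  expect_equal(sd(y3$hba1c, na.rm = TRUE), 1.35, tolerance = 0.15)
  expect_equal(sd(y3$bmi, na.rm = TRUE), 5.4, tolerance = 0.45)
})

test_that("inclusion criteria retain exactly the qualifying toy patients", {
  base <- function(id, dy, age, trt, smoke = 0, bmi = 28)
    data.frame(patient_id = id, year_of_diagnosis = dy,
               calendar_year = dy + 0:3, duration = 0:3,
               hba1c = 7, sbp = 140, bmi = bmi, tchdl = 4.5, ldl = 3,
               age_at_diagnosis = age, female = 0, smoking = smoke,
               treatment_class = trt)
  toy <- rbind(
    base(1, 2002, 55, "diet"),          # qualifies
    base(2, 2003, 40, "insulin"),       # qualifies (insulin at age >= 40)
    base(3, 2002, 24, "diet"),          # age below 25
    base(4, 2000, 55, "oha"),           # diagnosed before the window
    base(5, 2002, 35, "insulin"))       # insulin-treated, onset below 40
  kept <- apply_inclusion_criteria(toy)
  expect_setequal(unique(kept$patient_id), c(1, 2))
  # missing baseline BMI excludes a patient
  toy$bmi[toy$patient_id == 1 & toy$duration == 0] <- NA
  expect_setequal(unique(apply_inclusion_criteria(toy)$patient_id), 2)
  # the minimum-observation rule needs diagnosis-year data plus two
  # follow-up measurements of the target risk factor
  toy2 <- rbind(base(1, 2002, 55, "diet"), base(2, 2002, 55, "diet"))
  toy2$ldl[toy2$patient_id == 2 & toy2$duration >= 2] <- NA
  kept2 <- apply_inclusion_criteria(toy2, risk_factor = "ldl")
  expect_setequal(unique(kept2$patient_id), 1)
})

test_that("repeated within-year measurements average to the yearly mean", {
  meas <- data.frame(patient_id = c(1, 1, 1, 2),
                     calendar_year = c(2003, 2003, 2004, 2003),
                     sbp = c(140, 136, 150, 120),
                     hba1c = c(7, NA, 6, 8))
  out <- yearly_average(meas)
  expect_identical(nrow(out), 3L)
  expect_equal(out$sbp[out$patient_id == 1 & out$calendar_year == 2003], 138)
  # single readings pass through unchanged; no pooling across years
  expect_equal(out$sbp[out$patient_id == 1 & out$calendar_year == 2004], 150)
  expect_equal(out$sbp[out$patient_id == 2], 120)
  # missing readings are ignored within the year
  expect_equal(out$hba1c[out$patient_id == 1 & out$calendar_year == 2003], 7)
})

test_that("dropout produces unbalanced panels the estimator still handles", {
  pars <- cohort_params(n = 800, diagnosis_years = 2001, seed = 31,
                        dropout = 0.15)
  panel <- generate_cohort(pars)
  len <- tapply(panel$duration, panel$patient_id, max)
  expect_gt(mean(len < 7), 0.3)
  fit <- dpm_gmm(panel, ndr_model_spec("hba1c", max_lag = 4))
  expect_equal(coef(fit)[["lag_y"]], 0.526, tolerance = 0.08)
})
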