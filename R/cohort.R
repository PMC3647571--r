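## Seeded generator of register-like synthetic cohorts.
##
## The generator produces long-format unbalanced panels with the statistical
## structure of the dynamic equations: per-patient random effects mu_i, iid
## year shocks nu_it, baselines drawn per sex from the published register
## means/SDs, staggered diagnosis years, administrative end of follow-up,
## annual dropout and per-visit missingness.

## Register baseline moments in the year of diagnosis (total sample),
## by sex: mean and SD per risk factor, smoking prevalence, age.
.baseline_moments <- list(
  male = list(share = 2967 / 5043, age = c(56.0, 8.8), smoke = 0.21,
              hba1c = c(7.0, 1.4), sbp = c(138.5, 17.9), bmi = c(29.8, 4.9),
              tchdl = c(4.6, 1.4), ldl = c(3.1, 1.0)),
  female = list(share = 2076 / 5043, age = c(57.0, 9.0), smoke = 0.22,
                hba1c = c(6.9, 1.3), sbp = c(138.9, 18.2), bmi = c(30.7, 5.9),
                tchdl = c(4.4, 1.4), ldl = c(3.3, 1.0)))

## pooled target cross-sectional SD per factor, in equation (internal) units
.target_sd <- c(hba1c = 1.35, sbp = 1.805, tchdl = 1.4, ldl = 1.0, bmi = 5.4)

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the register cohort the equations were estimated on:
#' diagnoses staggered over 2001--2004, follow-up to the end of 2008,
#' baseline risk factors drawn per sex from the published means/SDs, and the
#' shipped coefficient set (all estimated coefficients, unfiltered) as the
#' data-generating truth.
#'
#' The error SDs are unpublished free parameters.  The defaults split each
#' factor's cross-sectional variance s^2 evenly between the permanent
#' patient effect and the transient component
#' (`sigma_mu = (1-alpha) s / sqrt(2)`, `sigma_nu = s sqrt((1-alpha^2)/2)`),
#' which makes the simulated cross-sectional SD equal to the register SD in
#' every follow-up year, not only at baseline.  Baselines are drawn as
#' `sex mean + mu_i/(1-alpha) + d_i`, i.e. they include each patient's
#' steady-state share of the permanent effect; this mean-stationarity is
#' what makes the levels-equation instruments of system GMM valid, and the
#' marginal baseline distribution still has the published mean and SD.
#'
#' @param n Number of patients.
#' @param diagnosis_years Calendar years of diagnosis to sample from.
#' @param followup_end Last calendar year of follow-up.
#' @param coefs True coefficient set (default: shipped set, unfiltered).
#' @param sigma_mu,sigma_nu Named numeric vectors (per risk factor) of the
#'   random-effect and shock SDs, in equation units (systolic BP on the /10
#'   scale); defaults as above.
#' @param dropout Annual probability that a patient permanently leaves
#'   follow-up.
#' @param missingness Probability that any one follow-up measurement is
#'   missing.
#' @param smoking_persistence Probabilities that baseline smoking status is
#'   unchanged over the whole follow-up, for baseline smokers and
#'   nonsmokers; non-persistent patients switch once at a uniformly drawn
#'   year.
#' @param seed Integer seed; every source of randomness in the generator
#'   flows from it.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n = 5043, diagnosis_years = 2001:2004,
                          followup_end = 2008, coefs = ndr_table2(),
                          sigma_mu = NULL, sigma_nu = NULL,
                          dropout = 0.05, missingness = 0.10,
                          smoking_persistence = c(smoker = 0.70,
                                                  nonsmoker = 0.95),
                          seed = NULL) {
  stopifnot(inherits(coefs, "rf_coefset"), n >= 1,
            dropout >= 0, dropout <= 1, missingness >= 0, missingness <= 1,
            all(smoking_persistence >= 0), all(smoking_persistence <= 1))
  alpha <- vapply(.rf_names, function(rf) coefs[[rf]]$lag$value, numeric(1))
  s <- .target_sd
  if (is.null(sigma_mu)) sigma_mu <- (1 - alpha) * s / sqrt(2)
  if (is.null(sigma_nu)) sigma_nu <- s * sqrt((1 - alpha^2) / 2)
  stopifnot(all(sigma_mu >= 0), all(sigma_nu >= 0))
  structure(list(n = as.integer(n), diagnosis_years = diagnosis_years,
                 followup_end = followup_end, coefs = coefs,
                 sigma_mu = sigma_mu[.rf_names], sigma_nu = sigma_nu[.rf_names],
                 dropout = dropout, missingness = missingness,
                 smoking_persistence = smoking_persistence, seed = seed),
            class = "cohort_params")
}

rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic register-like cohort
#'
#' Draws baselines per sex, then rolls the five coupled equations forward
#' with patient effects and year shocks: each year BMI is simulated first
#' and the simulated current-year BMI enters the other four equations.
#' Output is deterministic given the seed.
#'
#' @param params A [cohort_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return A long-format panel data frame with one row per attended
#'   patient-year: `patient_id`, `year_of_diagnosis`, `calendar_year`,
#'   `duration`, the five risk factors (systolic BP in mmHg), baseline
#'   covariates and current-year `smoking`, plus a `treatment_class` column
#'   used only by the inclusion filter.
#' @examples
#' panel <- generate_cohort(cohort_params(n = 50, seed = 42))
#' head(panel)
#' @export
generate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  coefs <- params$coefs
  mom <- .baseline_moments

  female <- stats::rbinom(n, 1, mom$female$share)
  sexnm <- ifelse(female == 1, "female", "male")
  draw_by_sex <- function(field, trunc_lo = -Inf, trunc_hi = Inf) {
    out <- numeric(n)
    for (sx in c("male", "female")) {
      idx <- sexnm == sx
      m <- mom[[sx]][[field]]
      out[idx] <- rtruncnorm(sum(idx), m[1], m[2], trunc_lo, trunc_hi)
    }
    out
  }
  age <- draw_by_sex("age", 25, 70)
  smoke0 <- stats::rbinom(n, 1, ifelse(female == 1, mom$female$smoke,
                                       mom$male$smoke))
  dy <- params$diagnosis_years
  diag_year <- dy[sample.int(length(dy), n, replace = TRUE)]
  Tn <- params$followup_end - diag_year
  tmax <- max(Tn)

  ## treatment class: crude age-dependent mix, used only by the inclusion
  ## filter (treatment never enters the equations)
  p_ins <- ifelse(age >= 40, 0.12, 0.35)
  u <- stats::runif(n)
  treatment <- ifelse(u < p_ins, "insulin",
                      ifelse(u < p_ins + 0.45, "oha", "diet"))

  alpha <- vapply(.rf_names, function(rf) coefs[[rf]]$lag$value, numeric(1))
  mu <- sapply(.rf_names, function(rf) stats::rnorm(n, 0, params$sigma_mu[[rf]]))
  s2 <- .target_sd^2
  ## baseline: sex mean + steady-state share of the patient effect + residual
  sd_resid <- sqrt(pmax(s2 - (params$sigma_mu / (1 - alpha))^2, 0))
  base <- sapply(.rf_names, function(rf) {
    m <- ifelse(female == 1, mom$female[[rf]][1], mom$male[[rf]][1])
    if (rf == "sbp") m <- m / 10                  # internal scale
    pmax(m + mu[, rf] / (1 - alpha[[rf]]) +
           stats::rnorm(n, 0, sd_resid[[rf]]), 1e-3)
  })

  ## smoking path: persistent patients keep baseline status; the rest switch
  ## once at a uniformly drawn follow-up year
  p_keep <- ifelse(smoke0 == 1, params$smoking_persistence[["smoker"]],
                   params$smoking_persistence[["nonsmoker"]])
  switches <- stats::rbinom(n, 1, 1 - p_keep) == 1
  switch_year <- ifelse(switches, 1 + floor(stats::runif(n) * pmax(Tn, 1)), Inf)

  rf_other <- setdiff(.rf_names, "bmi")
  vals <- lapply(.rf_names, function(rf) {
    m <- matrix(NA_real_, n, tmax + 1); m[, 1] <- base[, rf]; m
  })
  names(vals) <- .rf_names

  step_eq <- function(eq, prev, smoking_t, bmi_t, t, rf) {
    x <- cbind(ln_duration = log(t), year1 = as.numeric(t == 1),
               age_at_diagnosis = age, female = female, smoking = smoking_t,
               bmi = bmi_t, bmi_squared = bmi_t^2)
    out <- eq$lag$value * prev + term_value(eq$constant)
    for (nm in names(eq$covariates)) {
      b <- eq$covariates[[nm]]$value
      if (!is.null(b)) out <- out + b * x[, nm]
    }
    out + mu[, rf] + stats::rnorm(n, 0, params$sigma_nu[[rf]])
  }

  for (t in seq_len(tmax)) {
    smoking_t <- ifelse(t >= switch_year, 1 - smoke0, smoke0)
    bmi_prev <- vals$bmi[, t]
    bmi_t <- step_eq(coefs$bmi, bmi_prev, smoking_t, bmi_prev, t, "bmi")
    vals$bmi[, t + 1] <- bmi_t
    for (rf in rf_other)
      vals[[rf]][, t + 1] <- step_eq(coefs[[rf]], vals[[rf]][, t],
                                     smoking_t, bmi_t, t, rf)
  }

  ## attendance: administrative censoring at followup_end, then dropout
  last_t <- Tn
  if (params$dropout > 0)
    last_t <- pmin(Tn, stats::rgeom(n, params$dropout))

  rows <- lapply(0:tmax, function(t) {
    alive <- which(last_t >= t & Tn >= t)
    if (!length(alive)) return(NULL)
    smoking_t <- if (t == 0) smoke0[alive]
                 else ifelse(t >= switch_year[alive], 1 - smoke0[alive],
                             smoke0[alive])
    data.frame(patient_id = alive, year_of_diagnosis = diag_year[alive],
               calendar_year = diag_year[alive] + t, duration = t,
               hba1c = vals$hba1c[alive, t + 1],
               sbp = 10 * vals$sbp[alive, t + 1],
               bmi = vals$bmi[alive, t + 1],
               tchdl = vals$tchdl[alive, t + 1],
               ldl = vals$ldl[alive, t + 1],
               age_at_diagnosis = age[alive], female = female[alive],
               smoking = smoking_t, treatment_class = treatment[alive],
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$patient_id, panel$duration), ]
  rownames(panel) <- NULL

  if (params$missingness > 0) {
    fu <- panel$duration > 0
    for (rf in .rf_names) {
      hit <- fu & stats::runif(nrow(panel)) < params$missingness
      panel[[rf]][hit] <- NA_real_
    }
  }
  panel
}

#' Apply the register inclusion criteria to a panel
#'
#' Retains patients meeting the cohort definition: diagnosis within the
#' window, age 25--70 at diagnosis, non-missing smoking and BMI in the
#' diagnosis year, the type 2 diabetes treatment definition (diet or oral
#' agents at any age; insulin, alone or combined, only with age at onset of
#' at least 40), and -- when a target risk factor is named -- a measurement
#' at diagnosis plus at least `min_obs - 1` follow-up measurements.
#'
#' @param panel Long panel data frame.
#' @param risk_factor Optional risk-factor column for the minimum
#'   observation rule.
#' @param diagnosis_window Calendar-year window of eligible diagnoses.
#' @param age_range Eligible age at diagnosis.
#' @param min_obs Minimum number of non-missing measurements (including the
#'   diagnosis year) of `risk_factor`.
#' @return The filtered panel.
#' @export
apply_inclusion_criteria <- function(panel, risk_factor = NULL,
                                     diagnosis_window = c(2001, 2004),
                                     age_range = c(25, 70), min_obs = 3) {
  base <- panel[panel$duration == 0, ]
  ok <- base$year_of_diagnosis >= diagnosis_window[1] &
    base$year_of_diagnosis <= diagnosis_window[2] &
    base$age_at_diagnosis >= age_range[1] &
    base$age_at_diagnosis <= age_range[2] &
    !is.na(base$smoking) & !is.na(base$bmi)
  type2 <- base$treatment_class %in% c("diet", "oha") |
    (base$treatment_class %in% c("insulin", "insulin_oha") &
       base$age_at_diagnosis >= 40)
  ok <- ok & type2
  keep <- base$patient_id[ok]
  if (!is.null(risk_factor)) {
    stopifnot(risk_factor %in% names(panel))
    cnt <- tapply(!is.na(panel[[risk_factor]]), panel$patient_id, sum)
    at_base <- base$patient_id[!is.na(base[[risk_factor]])]
    enough <- as.numeric(names(cnt))[cnt >= min_obs]
    keep <- intersect(keep, intersect(enough, at_base))
  }
  panel[panel$patient_id %in% keep, , drop = FALSE]
}

#' Average repeated within-year measurements
#'
#' When a patient has several measurements in one calendar year, analyses
#' use the yearly mean.  Collapses a measurement-level table to one row per
#' patient-year, averaging each value column and carrying constant columns
#' through.
#'
#' @param measurements Data frame with `patient_id`, `calendar_year` and
#'   measurement columns.
#' @param values Columns to average; defaults to any of the five risk
#'   factors present.
#' @return One row per (patient, calendar year), means of `values` (missing
#'   readings ignored).
#' @export
yearly_average <- function(measurements,
                           values = intersect(.rf_names, names(measurements))) {
  stopifnot(all(c("patient_id", "calendar_year") %in% names(measurements)),
            length(values) > 0)
  key <- interaction(measurements$patient_id, measurements$calendar_year,
                     drop = TRUE)
  first <- !duplicated(key)
  keep <- setdiff(names(measurements), values)
  out <- measurements[first, keep, drop = FALSE]
  for (v in values)
    out[[v]] <- as.vector(tapply(measurements[[v]], key, mean,
                                 na.rm = TRUE))[match(key[first],
                                                      levels(key))]
  out[is.na(out)] <- NA                      # NaN from all-missing years
  rownames(out) <- NULL
  out
}
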