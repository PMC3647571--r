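## Patient baseline profiles.

#' Construct a patient baseline profile
#'
#' A profile records the characteristics of one (real or hypothetical)
#' patient in the year of type 2 diabetes diagnosis: demographics, smoking
#' status, and baseline values of the five risk factors.  It is the starting
#' point for [simulate_path()].
#'
#' @param age_at_diagnosis Age in years at diabetes diagnosis.
#' @param female 1 (or `TRUE`) for women, 0 for men.
#' @param smoker 1 (or `TRUE`) if smoking at diagnosis (at least one
#'   cigarette a day, daily pipe use, or quit within the previous 3 months).
#' @param hba1c Baseline HbA1c in % (DCCT standard).
#' @param sbp Baseline systolic blood pressure in mmHg.
#' @param bmi Baseline BMI in kg/m^2.
#' @param tchdl Baseline total:HDL cholesterol ratio.
#' @param ldl Baseline LDL cholesterol in mmol/L.
#' @param year_of_diagnosis Optional calendar year of diagnosis.
#' @param check_inclusion If `TRUE`, enforce the register inclusion window
#'   of 25--70 years of age at diagnosis.
#' @return An object of class `patient_profile`.
#' @examples
#' # the low-risk illustrative profile: nonsmoking woman, BMI 27, age 60
#' low <- patient_profile(age_at_diagnosis = 60, female = 1, smoker = 0,
#'                        hba1c = 7, sbp = 138, bmi = 27, tchdl = 4.5, ldl = 3)
#' @export
patient_profile <- function(age_at_diagnosis, female, smoker,
                            hba1c, sbp, bmi, tchdl, ldl,
                            year_of_diagnosis = NULL,
                            check_inclusion = FALSE) {
  female <- as.numeric(female); smoker <- as.numeric(smoker)
  stopifnot(female %in% c(0, 1), smoker %in% c(0, 1))
  vals <- c(hba1c = hba1c, sbp = sbp, bmi = bmi, tchdl = tchdl, ldl = ldl)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all baseline risk-factor values must be positive and finite",
         call. = FALSE)
  if (!is.finite(age_at_diagnosis) || age_at_diagnosis <= 0)
    stop("age_at_diagnosis must be positive", call. = FALSE)
  if (check_inclusion && (age_at_diagnosis < 25 || age_at_diagnosis > 70))
    stop("age at diagnosis outside the 25-70 year inclusion window",
         call. = FALSE)
  structure(list(age_at_diagnosis = age_at_diagnosis, female = female,
                 smoker = smoker, baseline = vals,
                 year_of_diagnosis = year_of_diagnosis),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("Patient profile: %s, age %g at diagnosis, %ssmoker\n",
              if (x$female == 1) "woman" else "man", x$age_at_diagnosis,
              if (x$smoker == 1) "" else "non"))
  cat(sprintf("  HbA1c %.2f %%, SBP %.1f mmHg, BMI %.1f kg/m2, TC:HDL %.2f, LDL %.2f mmol/L\n",
              x$baseline["hba1c"], x$baseline["sbp"], x$baseline["bmi"],
              x$baseline["tchdl"], x$baseline["ldl"]))
  invisible(x)
}

#' Build the covariate vector of the time-path equations
#'
#' Derives the model covariates for one patient-year: natural log of
#' diabetes duration, the first-year indicator, BMI and its square, plus the
#' frozen profile characteristics (age at diagnosis, sex).
#'
#' @param profile A [patient_profile()].
#' @param duration Years since diagnosis (integer, at least 1).
#' @param bmi_current Current-year BMI in kg/m^2; defaults to the profile
#'   baseline.
#' @param smoking_current Current-year smoking status; defaults to the
#'   profile baseline (the engine's default assumption is that baseline
#'   smoking status is stable).
#' @return A named numeric vector over [covariate_names()], with the
#'   duration kept as an attribute.
#' @examples
#' p <- patient_profile(60, 1, 0, 7, 138, 27, 4.5, 3)
#' build_covariates(p, duration = 1)       # ln_duration 0, year1 1
#' @export
build_covariates <- function(profile, duration,
                             bmi_current = profile$baseline[["bmi"]],
                             smoking_current = profile$smoker) {
  stopifnot(inherits(profile, "patient_profile"))
  if (!is.finite(duration) || duration < 1 || duration != round(duration))
    stop("duration must be an integer number of years >= 1", call. = FALSE)
  x <- c(ln_duration = log(duration),
         year1 = as.numeric(duration == 1),
         age_at_diagnosis = profile$age_at_diagnosis,
         female = profile$female,
         smoking = as.numeric(smoking_current),
         bmi = bmi_current,
         bmi_squared = bmi_current^2)
  attr(x, "duration") <- as.integer(duration)
  x
}
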