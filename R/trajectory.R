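## Deterministic trajectory engine for the coupled risk-factor equations.

#' One-step prediction from a single time-path equation
#'
#' Computes `alpha * previous + constant + sum_j beta_j x_j` for one
#' equation, using every coefficient that carries a numeric value (apply
#' [filter_significant()] first to restrict to significant covariates).
#' All arithmetic is in the equation's own modelling units; for systolic BP
#' that is the /10 scale.
#'
#' @param equation An `rf_equation` (one element of an `rf_coefset`).
#' @param previous_value Risk-factor value in the previous year, in equation
#'   units.
#' @param covariates Named numeric vector as from [build_covariates()];
#'   must supply a finite value for every retained covariate.
#' @return The predicted value, in equation units.
#' @export
predict_next <- function(equation, previous_value, covariates) {
  stopifnot(inherits(equation, "rf_equation"))
  out <- equation$lag$value * previous_value + term_value(equation$constant)
  for (nm in names(equation$covariates)) {
    beta <- equation$covariates[[nm]]$value
    if (is.null(beta)) next
    x <- if (nm %in% names(covariates)) covariates[[nm]] else NA_real_
    if (!is.finite(x))
      stop("equation '", equation$outcome, "' retains covariate '", nm,
           "' but no finite value for it was supplied", call. = FALSE)
    out <- out + beta * x
  }
  out
}

#' Simulate deterministic risk-factor paths for one patient
#'
#' Rolls the five coupled equations forward from a baseline profile.  Each
#' year BMI is updated first from its own equation; the current-year
#' predicted BMI (and its square) then enters the other four equations, so
#' that indirect covariate effects transmitted through BMI are included.
#' Smoking status is held at its baseline value unless an explicit
#' `smoking_path` is given.  Duration-dependent covariates (log duration,
#' first-year indicator) are recomputed every year; age at diagnosis and sex
#' are frozen.
#'
#' @param profile A [patient_profile()].
#' @param coefs An `rf_coefset`; defaults to the shipped NDR set.
#' @param horizon Number of years after diagnosis to simulate (>= 1).
#' @param level Significance filter passed to [filter_significant()];
#'   defaults to 0.10 (the convention used for prediction and validation).
#'   Use `"none"` to keep all estimated coefficients.
#' @param smoking_path Optional numeric vector of length `horizon` giving
#'   smoking status in years 1..horizon.
#' @return An object of class `rf_trajectory`: year-indexed values (year 0 =
#'   diagnosis baseline) for each risk factor in public units, plus the BMI
#'   and smoking paths used.
#' @examples
#' low <- patient_profile(60, 1, 0, hba1c = 7, sbp = 138, bmi = 27,
#'                        tchdl = 4.5, ldl = 3)
#' tr <- simulate_path(low, horizon = 5)
#' tr$values["bmi", ]   # 27.00 27.41 27.81 28.18 28.51 28.81
#' @export
simulate_path <- function(profile, coefs = ndr_table2(), horizon = 5,
                          level = 0.10, smoking_path = NULL) {
  stopifnot(inherits(profile, "patient_profile"), inherits(coefs, "rf_coefset"))
  if (!is.finite(horizon) || horizon < 1 || horizon != round(horizon))
    stop("horizon must be an integer number of years >= 1", call. = FALSE)
  horizon <- as.integer(horizon)
  coefs <- filter_significant(coefs, level)
  if (is.null(smoking_path)) smoking_path <- rep(profile$smoker, horizon)
  stopifnot(length(smoking_path) == horizon)

  rfs <- intersect(.rf_names, names(coefs))
  values <- matrix(NA_real_, length(rfs), horizon + 1,
                   dimnames = list(rfs, 0:horizon))
  values[, 1] <- profile$baseline[rfs]
  ## state held in equation (internal) units
  state <- mapply(function(rf) to_internal(coefs[[rf]], profile$baseline[[rf]]),
                  rfs)
  names(state) <- rfs

  for (t in seq_len(horizon)) {
    bmi_prev <- from_internal(coefs$bmi, state[["bmi"]])
    ## BMI first: its own equation uses last year's BMI only through the lag
    x_bmi <- build_covariates(profile, t, bmi_current = bmi_prev,
                              smoking_current = smoking_path[t])
    bmi_now <- predict_next(coefs$bmi, state[["bmi"]], x_bmi)
    state[["bmi"]] <- bmi_now
    ## other equations consume the same-year predicted BMI
    x_t <- build_covariates(profile, t,
                            bmi_current = from_internal(coefs$bmi, bmi_now),
                            smoking_current = smoking_path[t])
    for (rf in setdiff(rfs, "bmi"))
      state[[rf]] <- predict_next(coefs[[rf]], state[[rf]], x_t)
    values[, t + 1] <- vapply(rfs, function(rf)
      from_internal(coefs[[rf]], state[[rf]]), numeric(1))
  }

  structure(list(values = values, profile = profile, level = level,
                 smoking_path = smoking_path,
                 bmi_path = values["bmi", -1]),
            class = "rf_trajectory")
}

#' @export
print.rf_trajectory <- function(x, digits = 2, ...) {
  cat("Predicted risk-factor path (years since diagnosis; significance filter: ",
      format(x$level), ")\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' @export
as.data.frame.rf_trajectory <- function(x, ...) {
  data.frame(risk_factor = rep(rownames(x$values), times = ncol(x$values)),
             year = rep(as.integer(colnames(x$values)), each = nrow(x$values)),
             value = as.vector(x$values),
             stringsAsFactors = FALSE)
}

#' @export
plot.rf_trajectory <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  yrs <- as.integer(colnames(x$values))
  for (rf in rownames(x$values))
    graphics::plot(yrs, x$values[rf, ], type = "b", pch = 16,
                   xlab = "years since diagnosis", ylab = rf, main = rf, ...)
  invisible(x)
}

#' Long-term effect of a covariate in a first-order dynamic equation
#'
#' In the dynamic model the coefficient `beta` is the short-term (same-year)
#' effect of a one-unit covariate change; its cumulative effect over the
#' current and all future years is `beta / (1 - alpha)`, where `alpha` is
#' the coefficient on the lagged dependent variable.
#'
#' @param beta Short-term coefficient(s).
#' @param alpha Lag coefficient, strictly inside (0, 1).
#' @return `beta / (1 - alpha)`.
#' @examples
#' long_term_effect(0.182, 0.526)   # 0.384: ln-duration on HbA1c
#' @export
long_term_effect <- function(beta, alpha) {
  if (any(!is.finite(alpha)) || any(alpha >= 1) || any(alpha <= 0))
    stop("lag coefficient must lie strictly between 0 and 1; ",
         "no finite long-term effect otherwise", call. = FALSE)
  beta / (1 - alpha)
}

#' Long-term effects of every stored coefficient
#'
#' Applies [long_term_effect()] to each covariate (and the constant) of each
#' equation in a coefficient set.
#'
#' @param coefs An `rf_coefset`.
#' @return Data frame with columns `risk_factor`, `term`, `short_term`,
#'   `long_term`.
#' @export
long_term_effects <- function(coefs) {
  stopifnot(inherits(coefs, "rf_coefset"))
  do.call(rbind, lapply(names(coefs), function(nm) {
    eq <- coefs[[nm]]
    terms <- c(list(constant = eq$constant), eq$covariates)
    keep <- !vapply(terms, function(tm) is.null(tm$value), logical(1))
    terms <- terms[keep]
    if (!length(terms)) return(NULL)
    st <- vapply(terms, `[[`, numeric(1), "value")
    data.frame(risk_factor = nm, term = names(terms), short_term = st,
               long_term = long_term_effect(st, eq$lag$value),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Steady state of one equation under frozen covariates
#'
#' The fixed point of the recursion `v <- alpha v + constant + beta'x`:
#' `(constant + beta'x) / (1 - alpha)`.  Applying [predict_next()] at the
#' steady state with the same covariates returns it unchanged, and the path
#' approaches it geometrically at rate `alpha`.
#'
#' @param equation An `rf_equation`.
#' @param covariates Named covariate vector (frozen).
#' @return Steady-state value in equation units.
#' @export
steady_state <- function(equation, covariates) {
  stopifnot(inherits(equation, "rf_equation"))
  a <- equation$lag$value
  if (!is.finite(a) || a >= 1 || a <= 0)
    stop("lag coefficient must lie strictly between 0 and 1", call. = FALSE)
  ## predict_next from 0 gives the forcing term constant + beta'x
  predict_next(equation, 0, covariates) / (1 - a)
}
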