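## Temporal external validation: observed-on-predicted regression and
## RMSE-based comparison of candidate coefficient sets.

#' Predict risk-factor paths for every patient of a panel
#'
#' Rolls the trajectory engine forward from each patient's diagnosis-year
#' baseline and aligns the predictions with the observed patient-years, up
#' to `horizon` years after diagnosis.  Patients without a complete
#' diagnosis-year baseline (all five risk factors, smoking and BMI) are
#' skipped; their count is attached as the `skipped` attribute.
#'
#' @param panel Long panel data frame (see [generate_cohort()] for the
#'   schema); systolic BP in mmHg.
#' @param coefs Coefficient set used for prediction.
#' @param level Significance filter for prediction (default 0.10, the
#'   validation convention).
#' @param horizon Years after diagnosis to predict (default 3).
#' @return Data frame with `patient_id`, `duration`, `risk_factor`,
#'   `observed`, `predicted` (rows limited to observed, non-missing
#'   patient-years).
#' @export
predict_for_panel <- function(panel, coefs = ndr_table2(), level = 0.10,
                              horizon = 3) {
  base <- panel[panel$duration == 0, ]
  complete <- stats::complete.cases(base[, c(.rf_names, "age_at_diagnosis",
                                             "female", "smoking")])
  skipped <- sum(!complete)
  base <- base[complete, ]
  fu <- panel[panel$duration >= 1 & panel$duration <= horizon &
                panel$patient_id %in% base$patient_id, ]
  coefs <- filter_significant(coefs, level)

  preds <- lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    prof <- patient_profile(b$age_at_diagnosis, b$female, b$smoking,
                            hba1c = b$hba1c, sbp = b$sbp, bmi = b$bmi,
                            tchdl = b$tchdl, ldl = b$ldl)
    tr <- simulate_path(prof, coefs, horizon = horizon, level = "none")
    df <- as.data.frame(tr)
    df <- df[df$year >= 1, ]
    df$patient_id <- b$patient_id
    df
  })
  pred <- do.call(rbind, preds)
  obs <- stats::reshape(fu[, c("patient_id", "duration", .rf_names)],
                        direction = "long", varying = .rf_names,
                        v.names = "observed", timevar = "risk_factor",
                        times = .rf_names, idvar = c("patient_id", "duration"))
  out <- merge(obs, pred,
               by.x = c("patient_id", "duration", "risk_factor"),
               by.y = c("patient_id", "year", "risk_factor"))
  out <- out[!is.na(out$observed), c("patient_id", "duration", "risk_factor",
                                     "observed", "predicted" = "value")]
  names(out)[names(out) == "value"] <- "predicted"
  out <- out[order(out$patient_id, out$duration, out$risk_factor), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Regress observed on predicted values
#'
#' Ordinary least-squares fit of observed on predicted values with a
#' one-sided test of positive association (null: slope <= 0).
#'
#' @param observed,predicted Paired numeric vectors (at least 3 pairs).
#' @return List with `slope`, `intercept`, `p.value` (one-sided), `n`.
#' @export
regress_obs_on_pred <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(predicted) == 0)
    stop("predictions have zero variance; the slope is undefined",
         call. = FALSE)
  ## closed-form simple OLS: in the noise-free self-consistency limit the
  ## residual variance is exactly zero and the t statistic is infinite,
  ## which lm()'s summary would warn about
  n <- length(observed)
  vx <- stats::var(predicted)
  slope <- stats::cov(predicted, observed) / vx
  intercept <- mean(observed) - slope * mean(predicted)
  rss <- sum((observed - intercept - slope * predicted)^2)
  se <- sqrt(rss / (n - 2) / ((n - 1) * vx))
  tstat <- if (se == 0) sign(slope) * Inf else slope / se
  list(slope = slope, intercept = intercept,
       p.value = stats::pt(tstat, df = n - 2, lower.tail = FALSE),
       n = n)
}

#' Root mean squared error
#'
#' @param observed,predicted Paired numeric vectors of equal length.
#' @return `sqrt(mean((observed - predicted)^2))` over non-missing pairs.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  ok <- is.finite(observed) & is.finite(predicted)
  if (!any(ok)) stop("rmse undefined on empty input", call. = FALSE)
  sqrt(mean((observed[ok] - predicted[ok])^2))
}

#' Compare candidate coefficient sets by prediction error
#'
#' Computes the RMSE of each named prediction set against the same observed
#' values and ranks the models.
#'
#' @param observed Observed values.
#' @param predictions_by_model Named list of at least two prediction vectors
#'   aligned with `observed`.
#' @return Data frame with `model`, `rmse`, `rank` (1 = smallest error).
#' @export
compare_models <- function(observed, predictions_by_model) {
  if (!is.list(predictions_by_model) || length(predictions_by_model) < 2)
    stop("need at least two named prediction sets to compare", call. = FALSE)
  if (is.null(names(predictions_by_model)) ||
      any(names(predictions_by_model) == ""))
    stop("prediction sets must be named", call. = FALSE)
  lens <- vapply(predictions_by_model, length, integer(1))
  if (any(lens != length(observed)))
    stop("prediction sets are not aligned with the observed values",
         call. = FALSE)
  errs <- vapply(predictions_by_model, rmse, numeric(1), observed = observed)
  out <- data.frame(model = names(errs), rmse = unname(errs),
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$rmse, ties.method = "min")
  out[order(out$rank), ]
}

#' Temporal external validation of a coefficient set
#'
#' Runs the full validation pipeline on a held-out panel: per risk factor
#' and subgroup (sex by baseline smoking status, plus the whole sample),
#' the observed-on-predicted regression with its one-sided p-value and the
#' RMSE of each candidate coefficient set.
#'
#' @param panel Held-out long panel.
#' @param coefs Primary coefficient set.
#' @param comparator Optional named list of alternative coefficient sets
#'   (e.g. an external model supplied by the user).
#' @param level Significance filter for prediction.
#' @param horizon Validation horizon in years after diagnosis (default 3).
#' @return Object of class `rf_validation`: a data frame with one row per
#'   risk factor x subgroup x model.
#' @export
validate_panel <- function(panel, coefs = ndr_table2(), comparator = NULL,
                           level = 0.10, horizon = 3) {
  models <- c(list(primary = coefs), comparator)
  preds <- lapply(models, function(cs)
    predict_for_panel(panel, cs, level = level, horizon = horizon))
  ref <- preds[[1]]

  base <- panel[panel$duration == 0, c("patient_id", "female", "smoking")]
  ref$female <- base$female[match(ref$patient_id, base$patient_id)]
  ref$smoker0 <- base$smoking[match(ref$patient_id, base$patient_id)]
  groups <- list(all = rep(TRUE, nrow(ref)))
  for (f in 0:1) for (s in 0:1)
    groups[[paste0(ifelse(f == 1, "female_", "male_"),
                   ifelse(s == 1, "smoker", "nonsmoker"))]] <-
      ref$female == f & ref$smoker0 == s

  rows <- list()
  for (rf in unique(ref$risk_factor)) for (gnm in names(groups)) {
    sel <- groups[[gnm]] & ref$risk_factor == rf
    if (sum(sel) < 3) next
    obs <- ref$observed[sel]
    for (mnm in names(models)) {
      p <- preds[[mnm]]
      psel <- p$predicted[match(paste(ref$patient_id[sel], ref$duration[sel],
                                      ref$risk_factor[sel]),
                                paste(p$patient_id, p$duration,
                                      p$risk_factor))]
      reg <- tryCatch(regress_obs_on_pred(obs, psel),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        risk_factor = rf, subgroup = gnm, model = mnm,
        n = length(unique(ref$patient_id[sel])),
        slope = if (is.null(reg)) NA_real_ else reg$slope,
        intercept = if (is.null(reg)) NA_real_ else reg$intercept,
        p_one_sided = if (is.null(reg)) NA_real_ else reg$p.value,
        rmse = rmse(obs, psel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  attr(out, "skipped") <- attr(ref, "skipped")
  class(out) <- c("rf_validation", "data.frame")
  out
}

#' @export
print.rf_validation <- function(x, ...) {
  cat("Temporal external validation (horizon ", attr(x, "horizon"),
      " years; ", attr(x, "skipped"), " patients without baseline skipped)\n",
      sep = "")
  print.data.frame(cbind(x[, c("risk_factor", "subgroup", "model", "n")],
                         round(x[, c("slope", "intercept", "p_one_sided",
                                     "rmse")], 4)))
  invisible(x)
}
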