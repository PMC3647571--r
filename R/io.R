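## Panel and report file I/O.

.panel_cols <- c("patient_id", "year_of_diagnosis", "calendar_year",
                 "duration", "hba1c", "sbp", "bmi", "tchdl", "ldl",
                 "age_at_diagnosis", "female", "smoking", "treatment_class")

#' Read a long-format patient panel from delimited text
#'
#' Expects a CSV with the documented header (`patient_id`,
#' `year_of_diagnosis`, `calendar_year`, `duration`, the five risk factors,
#' `age_at_diagnosis`, `female`, `smoking`, `treatment_class`); missing
#' values as empty cells.  `duration` may be omitted, in which case it is
#' derived; when present it is cross-checked against
#' `calendar_year - year_of_diagnosis`.
#'
#' @param path CSV file path.
#' @param hba1c_standard `"dcct"` (default) if HbA1c values are already on
#'   the DCCT standard, `"monos"` to convert Swedish Mono-S values on load.
#' @return Validated panel data frame.
#' @export
read_panel <- function(path, hba1c_standard = c("dcct", "monos")) {
  hba1c_standard <- match.arg(hba1c_standard)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(.panel_cols, c("duration", "treatment_class"))
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  derived <- panel$calendar_year - panel$year_of_diagnosis
  if (is.null(panel$duration)) panel$duration <- derived
  bad <- which(panel$duration != derived)
  if (length(bad))
    stop("inconsistent duration (should equal calendar_year - ",
         "year_of_diagnosis) in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(panel$duration < 0) || any(panel$duration != round(panel$duration)))
    stop("duration must be a non-negative integer", call. = FALSE)
  key <- paste(panel$patient_id, panel$duration)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, duration) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  if (hba1c_standard == "monos") {
    ok <- !is.na(panel$hba1c)
    panel$hba1c[ok] <- hba1c_monos_to_dcct(panel$hba1c[ok])
  }
  panel
}

#' Write a tabular report to delimited text
#'
#' Deterministic column order, at least 15 significant digits, empty cells
#' for missing values; writing the same report twice yields identical
#' files.
#'
#' @param report Data frame (e.g. a trajectory table, a panel, or an
#'   `rf_validation` report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report <- as.data.frame(report)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  old <- options(digits = 15, scipen = 100)
  on.exit(options(old), add = TRUE)
  utils::write.csv(report, con, row.names = FALSE, na = "")
  invisible(path)
}
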