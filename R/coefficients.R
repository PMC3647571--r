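## Coefficient sets for the five first-order risk-factor equations.
##
## Each equation has the form
##   RF_t = alpha * RF_{t-1} + sum_j beta_j x_{jt} + constant + error
## with RF one of HbA1c, systolic BP (modelled on the /10 scale), TC:HDL,
## LDL cholesterol or BMI, and x_j drawn from a fixed covariate dictionary.

.rf_names <- c("hba1c", "sbp", "tchdl", "ldl", "bmi")

.cov_names <- c("ln_duration", "year1", "age_at_diagnosis", "female",
                "smoking", "bmi", "bmi_squared")

.sig_codes <- c("1%", "5%", "10%", "ns", "ni")

## numeric threshold attained by each marker; ns/ni never pass a filter
.sig_threshold <- c("1%" = 0.01, "5%" = 0.05, "10%" = 0.10, "ns" = Inf, "ni" = Inf)

#' Risk factors known to the equation system
#'
#' @return Character vector of the five risk-factor identifiers, in the
#'   order used throughout the package: `"hba1c"`, `"sbp"`, `"tchdl"`,
#'   `"ldl"`, `"bmi"`.
#' @export
risk_factors <- function() .rf_names

#' Covariate dictionary of the time-path equations
#'
#' @return Character vector of covariate names an equation may use:
#'   log diabetes duration, first-year indicator, age at diagnosis, female
#'   sex, current smoking, current BMI and its square.
#' @export
covariate_names <- function() .cov_names

new_rf_equation <- function(outcome, label, scale, constant, lag, covariates,
                            meta = list()) {
  eq <- list(outcome = outcome, label = label, scale = scale,
             constant = constant, lag = lag, covariates = covariates,
             meta = meta)
  class(eq) <- "rf_equation"
  eq
}

validate_term <- function(term, where) {
  if (is.null(term$sig) || !term$sig %in% .sig_codes)
    stop("coefficient file: missing or unknown significance marker in '",
         where, "' (must be one of ", paste(.sig_codes, collapse = ", "), ")",
         call. = FALSE)
  if (term$sig == "ni") {
    if (!is.null(term$value))
      stop("coefficient file: '", where,
           "' is marked not-included but carries a value", call. = FALSE)
  } else if (term$sig != "ns" && (is.null(term$value) || !is.numeric(term$value)))
    stop("coefficient file: missing numeric value in '", where, "'",
         call. = FALSE)
  if (!is.null(term$value) && !is.finite(term$value))
    stop("coefficient file: non-finite value in '", where, "'", call. = FALSE)
  term
}

validate_equation <- function(eq) {
  validate_term(eq$constant, paste0(eq$outcome, ":constant"))
  validate_term(eq$lag, paste0(eq$outcome, ":lag"))
  if (is.null(eq$lag$value) || eq$lag$value <= 0 || eq$lag$value >= 1)
    stop("equation '", eq$outcome, "': lag coefficient must lie strictly ",
         "between 0 and 1 (got ",
         if (is.null(eq$lag$value)) "none" else format(eq$lag$value),
         "); the dynamic model converges only for |alpha| < 1", call. = FALSE)
  bad <- setdiff(names(eq$covariates), .cov_names)
  if (length(bad))
    stop("equation '", eq$outcome, "': unknown covariate(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  for (nm in names(eq$covariates))
    validate_term(eq$covariates[[nm]], paste0(eq$outcome, ":", nm))
  invisible(eq)
}

#' Read a risk-factor coefficient set from a structured text file
#'
#' Coefficient sets are stored as YAML with one block per equation; see the
#' shipped default `ndr_table2.yaml` under `inst/extdata` for the schema and
#' an annotated example.  Every file is validated on load: significance
#' markers must be known, not-included terms must carry no value, and each
#' lag coefficient must lie strictly inside (0, 1).
#'
#' @param path Path to a YAML coefficient file.
#' @return An object of class `rf_coefset`: a named list of `rf_equation`
#'   objects (one per risk factor present in the file).
#' @seealso [ndr_table2()] for the shipped default, [write_coefset()],
#'   [filter_significant()].
#' @export
read_coefset <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!length(raw) || !is.list(raw))
    stop("coefficient file: no equation blocks found in ", path, call. = FALSE)
  eqs <- lapply(names(raw), function(nm) {
    blk <- raw[[nm]]
    for (fld in c("constant", "lag"))
      if (is.null(blk[[fld]]))
        stop("coefficient file: equation '", nm, "' lacks the '", fld,
             "' block", call. = FALSE)
    covs <- blk$covariates
    if (is.null(covs)) covs <- list()
    eq <- new_rf_equation(outcome = nm,
                          label = if (is.null(blk$label)) nm else blk$label,
                          scale = if (is.null(blk$scale)) 1 else blk$scale,
                          constant = blk$constant, lag = blk$lag,
                          covariates = covs,
                          meta = if (is.null(blk$meta)) list() else blk$meta)
    validate_equation(eq)
    eq
  })
  names(eqs) <- names(raw)
  structure(eqs, class = "rf_coefset", sig_level = "none")
}

#' Write a coefficient set back to structured text
#'
#' Inverse of [read_coefset()]; the default set round-trips bit-identically.
#'
#' @param x An `rf_coefset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefset <- function(x, path) {
  stopifnot(inherits(x, "rf_coefset"))
  out <- lapply(unclass(x), function(eq)
    Filter(Negate(is.null),
           list(label = eq$label, scale = eq$scale, constant = eq$constant,
                lag = eq$lag, covariates = eq$covariates,
                meta = if (length(eq$meta)) eq$meta else NULL)))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

.coef_cache <- new.env(parent = emptyenv())

#' The shipped NDR coefficient set
#'
#' Returns the default coefficient set for the five risk-factor equations,
#' estimated by system GMM on Swedish National Diabetes Register patients
#' newly diagnosed with type 2 diabetes in 2001--2004.  Values are stored in
#' a plain-text file under `inst/extdata` and validated on first use.
#'
#' Units: HbA1c in % (DCCT standard), systolic BP equations operate on the
#' mmHg/10 scale, LDL in mmol/L, BMI in kg/m^2, TC:HDL dimensionless.
#' Significance markers distinguish coefficients significant at 1/5/10%,
#' estimated but not significant (`"ns"`, e.g. smoking in the HbA1c
#' equation), and not included in an equation (`"ni"`).
#'
#' @return An `rf_coefset` with equations `hba1c`, `sbp`, `tchdl`, `ldl`,
#'   `bmi`.
#' @examples
#' cs <- ndr_table2()
#' cs$hba1c$lag$value          # 0.526
#' long_term_effect(cs$hba1c$covariates$ln_duration$value, cs$hba1c$lag$value)
#' @export
ndr_table2 <- function() {
  if (is.null(.coef_cache$table2)) {
    path <- system.file("extdata", "ndr_table2.yaml", package = "ndrpath",
                        mustWork = TRUE)
    .coef_cache$table2 <- read_coefset(path)
  }
  .coef_cache$table2
}

term_value <- function(term) if (is.null(term$value)) NA_real_ else term$value

## is a term retained under a numeric significance level (or "none")?
term_used <- function(term, level) {
  if (is.null(term$value)) return(FALSE)       # "ni" or valueless "ns"
  if (identical(level, "none")) return(TRUE)
  .sig_threshold[[term$sig]] <= level + 1e-12
}

#' Keep only covariates significant at a given level
#'
#' Prediction follows the convention of the source model's temporal
#' validation: covariate coefficients whose attained significance is weaker
#' than `level` are zeroed, while the constant and the lag coefficient are
#' always retained.  `level = "none"` keeps every coefficient that carries a
#' numeric value (including non-significant ones), for sensitivity analysis.
#' The operation is idempotent.
#'
#' @param coefs An `rf_coefset`.
#' @param level One of 0.01, 0.05, 0.10, or `"none"`.
#' @return An `rf_coefset` in which filtered-out covariates have their value
#'   removed (marker preserved).
#' @examples
#' f <- filter_significant(ndr_table2(), 0.10)
#' f$bmi$covariates$female$value   # NULL: 0.134 is unstarred, filtered out
#' @export
filter_significant <- function(coefs, level = 0.10) {
  stopifnot(inherits(coefs, "rf_coefset"))
  if (!identical(level, "none")) {
    if (!is.numeric(level) || !any(abs(level - c(0.01, 0.05, 0.10)) < 1e-9))
      stop("level must be 0.01, 0.05, 0.10 or \"none\"", call. = FALSE)
    for (nm in names(coefs)) {
      covs <- coefs[[nm]]$covariates
      for (cv in names(covs))
        if (!is.null(covs[[cv]]$value) && !term_used(covs[[cv]], level))
          covs[[cv]][["value"]] <- NULL
      coefs[[nm]]$covariates <- covs
    }
  }
  attr(coefs, "sig_level") <- level
  coefs
}

#' @export
print.rf_equation <- function(x, ...) {
  cat(x$label, "\n")
  if (x$scale != 1)
    cat("  (dependent variable modelled as value/", x$scale, ")\n", sep = "")
  rows <- rbind(
    data.frame(term = "constant", value = term_value(x$constant),
               sig = x$constant$sig),
    data.frame(term = "lag", value = term_value(x$lag), sig = x$lag$sig),
    do.call(rbind, lapply(names(x$covariates), function(nm)
      data.frame(term = nm, value = term_value(x$covariates[[nm]]),
                 sig = x$covariates[[nm]]$sig))))
  print(rows, row.names = FALSE)
  invisible(x)
}

#' @export
print.rf_coefset <- function(x, ...) {
  cat("Risk-factor time-path coefficient set (",
      length(x), " equations; significance filter: ",
      format(attr(x, "sig_level")), ")\n\n", sep = "")
  for (eq in x) { print(eq); cat("\n") }
  invisible(x)
}
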