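## Blundell-Bond system GMM for first-order dynamic panel equations.
##
## The model is  y_it = alpha y_{i,t-1} + beta' x_it + mu_i + nu_it.
## Estimation stacks two sets of moment conditions:
##   * differenced equation, instrumented by lagged levels (lags >= 2 of the
##     dependent variable and of endogenous regressors, lags >= 1 of
##     predetermined regressors) and by the differences of strictly
##     exogenous regressors;
##   * levels equation, instrumented by lagged differences (Delta y_{t-1},
##     Delta x_t for predetermined, Delta x_{t-1} for endogenous) and by the
##     exogenous regressors themselves.
## Moment conditions are formed from whatever valid (t, lag) pairs exist per
## patient, so unbalanced panels and gaps are handled naturally.

#' Specify a dynamic panel equation
#'
#' Classifies each regressor of a dynamic risk-factor equation for
#' instrument construction.  The lagged dependent variable is always treated
#' as predetermined.
#'
#' @param dependent Column name of the dependent variable.
#' @param exogenous Strictly exogenous regressors (uncorrelated with past,
#'   present and future shocks); time-invariant columns belong here.
#' @param predetermined Regressors possibly correlated with past shocks
#'   (instrumented from lag 1 in the differenced equation).
#' @param endogenous Regressors possibly correlated with contemporaneous
#'   shocks (instrumented from lag 2).
#' @param max_lag Deepest instrument lag used (default all available).
#' @param collapse If `TRUE` (default) collapse the instrument matrix to one
#'   column per (variable, lag) instead of one per (variable, lag, period),
#'   guarding against instrument proliferation.
#' @param twostep If `TRUE` (default) use two-step GMM with
#'   Windmeijer-corrected standard errors.
#' @return An object of class `dpm_spec`.
#' @seealso [ndr_model_spec()] for the shipped per-risk-factor defaults.
#' @export
model_spec <- function(dependent, exogenous = character(),
                       predetermined = character(), endogenous = character(),
                       max_lag = Inf, collapse = TRUE, twostep = TRUE) {
  regs <- c(exogenous, predetermined, endogenous)
  if (anyDuplicated(regs))
    stop("a regressor may appear in only one classification", call. = FALSE)
  if (dependent %in% regs)
    stop("the dependent variable cannot also be a regressor (its lag is ",
         "added automatically)", call. = FALSE)
  if (!is.numeric(max_lag) || max_lag < 1)
    stop("max_lag must be >= 1", call. = FALSE)
  structure(list(dependent = dependent, exogenous = exogenous,
                 predetermined = predetermined, endogenous = endogenous,
                 max_lag = max_lag, collapse = isTRUE(collapse),
                 twostep = isTRUE(twostep)),
            class = "dpm_spec")
}

#' Default equation specifications for the NDR risk factors
#'
#' Mirrors the published estimation set-up: log diabetes duration, age at
#' diagnosis and sex are strictly exogenous; current BMI (and its square,
#' in the LDL equation) is predetermined; smoking is endogenous in the
#' HbA1c equation and exogenous elsewhere; the HbA1c equation carries the
#' first-year indicator.
#'
#' @param risk_factor One of [risk_factors()].
#' @param ... Passed on to [model_spec()] (e.g. `max_lag`, `collapse`).
#' @return A `dpm_spec`.
#' @export
ndr_model_spec <- function(risk_factor = risk_factors(), ...) {
  rf <- match.arg(risk_factor)
  exo <- c("ln_duration", "age_at_diagnosis", "female")
  if (rf == "hba1c") exo <- c(exo, "year1")
  endo <- character()
  if (rf == "hba1c") endo <- "smoking" else exo <- c(exo, "smoking")
  pre <- character()
  if (rf != "bmi") pre <- "bmi"
  if (rf == "ldl") pre <- c(pre, "bmi_squared")
  model_spec(rf, exogenous = exo, predetermined = pre, endogenous = endo, ...)
}

## wide (patient x period) value matrix from a long panel
panel_wide <- function(panel, var, ids, tmax) {
  m <- matrix(NA_real_, length(ids), tmax + 1,
              dimnames = list(ids, 0:tmax))
  v <- panel[[var]]
  m[cbind(match(panel$patient_id, ids), panel$duration + 1L)] <- v
  m
}

## add derived regressors if referenced but absent
add_derived <- function(panel, vars) {
  if ("ln_duration" %in% vars && is.null(panel$ln_duration))
    panel$ln_duration <- log(pmax(panel$duration, 1))
  if ("year1" %in% vars && is.null(panel$year1))
    panel$year1 <- as.numeric(panel$duration == 1)
  if ("bmi_squared" %in% vars && is.null(panel$bmi_squared))
    panel$bmi_squared <- panel$bmi^2
  panel
}

#' First-difference a panel variable
#'
#' Computes `x_it - x_i,t-1` wherever consecutive observations exist;
#' records without an immediate predecessor (including those across gaps)
#' are dropped.
#'
#' @param panel Long panel data frame with `patient_id` and integer
#'   `duration` columns.
#' @param variable Column to difference.
#' @return Data frame with `patient_id`, `duration` and the differenced
#'   value (named `d<variable>`).
#' @export
first_difference <- function(panel, variable) {
  stopifnot(variable %in% names(panel))
  panel <- panel[order(panel$patient_id, panel$duration), ]
  same <- c(FALSE, panel$patient_id[-1] == panel$patient_id[-nrow(panel)])
  consec <- same & c(FALSE, diff(panel$duration) == 1)
  keep <- which(consec)
  out <- data.frame(patient_id = panel$patient_id[keep],
                    duration = panel$duration[keep])
  out[[paste0("d", variable)]] <-
    panel[[variable]][keep] - panel[[variable]][keep - 1L]
  out
}

#' Build the system-GMM design for a dynamic panel equation
#'
#' Constructs the stacked regressor matrix, instrument matrix and row
#' bookkeeping for the differenced and levels equations implied by a
#' [model_spec()].  Exposed mainly for inspection and testing; [dpm_gmm()]
#' calls it internally.
#'
#' @param panel Long panel data frame (`patient_id`, integer `duration`
#'   from 0 at diagnosis, dependent and regressor columns; `ln_duration`,
#'   `year1` and `bmi_squared` are derived on the fly when referenced).
#' @param spec A `dpm_spec`.
#' @return A list with elements `y`, `X` (first column the lagged dependent
#'   variable, last the constant), `Z` (instruments), `rows` (patient,
#'   period, part) and `cols` (instrument descriptors: part, variable, lag,
#'   period, type).
#' @export
build_instruments <- function(panel, spec) {
  stopifnot(inherits(spec, "dpm_spec"))
  regs <- c(spec$exogenous, spec$predetermined, spec$endogenous)
  panel <- add_derived(panel, regs)
  need <- c("patient_id", "duration", spec$dependent, regs)
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(panel$duration != round(panel$duration)))
    stop("duration must be integer years since diagnosis", call. = FALSE)

  ids <- unique(panel$patient_id)
  tmax <- max(panel$duration)
  if (tmax < 2)
    stop("estimation impossible: need at least 3 periods (t = 0, 1, 2) of ",
         "the dependent variable", call. = FALSE)
  Y <- panel_wide(panel, spec$dependent, ids, tmax)
  Xw <- lapply(regs, panel_wide, panel = panel, ids = ids, tmax = tmax)
  names(Xw) <- regs
  maxlag <- min(spec$max_lag, tmax)
  k <- length(regs) + 2L                     # lag y + regressors + constant

  rows <- list(); Xrows <- list(); yrows <- list()
  zvals <- list()  # per column name: list of (row-chunk values)
  colmeta <- list()

  add_z <- function(chunk_id, colkey, values, meta) {
    if (is.null(zvals[[colkey]])) {
      zvals[[colkey]] <<- list()
      colmeta[[colkey]] <<- meta
    }
    zvals[[colkey]][[chunk_id]] <<- values
  }

  ok_row <- function(tt, lagged = FALSE) {
    ok <- is.finite(Y[, tt + 1]) & is.finite(Y[, tt])
    for (r in regs) ok <- ok & is.finite(Xw[[r]][, tt + 1])
    if (lagged) {
      ok <- ok & is.finite(Y[, tt - 1])
      for (r in regs) ok <- ok & is.finite(Xw[[r]][, tt])
    }
    ok
  }

  chunk <- 0L
  ## ---- differenced equation rows, t = 2..tmax ----
  for (tt in 2:tmax) {
    ok <- which(ok_row(tt, lagged = TRUE))
    if (!length(ok)) next
    chunk <- chunk + 1L
    cid <- sprintf("d%02d", tt)
    rows[[cid]] <- data.frame(patient = ids[ok], t = tt, part = "diff",
                              stringsAsFactors = FALSE)
    dy <- Y[ok, tt + 1] - Y[ok, tt]
    dylag <- Y[ok, tt] - Y[ok, tt - 1]
    dX <- matrix(0, length(ok), length(regs), dimnames = list(NULL, regs))
    for (r in regs) dX[, r] <- Xw[[r]][ok, tt + 1] - Xw[[r]][ok, tt]
    yrows[[cid]] <- dy
    Xrows[[cid]] <- cbind(lag_y = dylag, dX, constant = 0)
    ## GMM-style instruments: lagged levels
    gmm_cols <- function(var, M, lmin) {
      lmax <- min(tt, maxlag)
      if (lmax < lmin) return(invisible())
      for (l in lmin:lmax) {
        src <- tt - l
        if (src < 0) next
        v <- M[ok, src + 1]; v[!is.finite(v)] <- 0
        key <- if (spec$collapse) sprintf("D.%s.L%d", var, l)
               else sprintf("D.%s.L%d.t%d", var, l, tt)
        add_z(cid, key, v, data.frame(part = "diff", variable = var, lag = l,
                                      period = if (spec$collapse) NA_integer_ else tt,
                                      type = "gmm", stringsAsFactors = FALSE))
      }
    }
    gmm_cols(spec$dependent, Y, 2L)
    for (r in spec$predetermined) gmm_cols(r, Xw[[r]], 1L)
    for (r in spec$endogenous) gmm_cols(r, Xw[[r]], 2L)
    ## IV-style: differences of exogenous regressors
    for (r in spec$exogenous) {
      v <- Xw[[r]][ok, tt + 1] - Xw[[r]][ok, tt]; v[!is.finite(v)] <- 0
      add_z(cid, sprintf("D.%s.iv", r), v,
            data.frame(part = "diff", variable = r, lag = 0L,
                       period = NA_integer_, type = "iv",
                       stringsAsFactors = FALSE))
    }
  }
  if (!length(rows))
    stop("estimation impossible: no usable differenced observations ",
         "(need >= 3 consecutive periods for some patient)", call. = FALSE)

  ## ---- levels equation rows, t = 1..tmax ----
  for (tt in 1:tmax) {
    ok <- which(ok_row(tt))
    if (!length(ok)) next
    chunk <- chunk + 1L
    cid <- sprintf("l%02d", tt)
    rows[[cid]] <- data.frame(patient = ids[ok], t = tt, part = "levels",
                              stringsAsFactors = FALSE)
    yrows[[cid]] <- Y[ok, tt + 1]
    Xl <- matrix(0, length(ok), length(regs), dimnames = list(NULL, regs))
    for (r in regs) Xl[, r] <- Xw[[r]][ok, tt + 1]
    Xrows[[cid]] <- cbind(lag_y = Y[ok, tt], Xl, constant = 1)
    lag_diff <- function(var, M, shift) {
      ## Delta var at period tt - shift
      hi <- tt - shift; lo <- hi - 1
      if (lo < 0) return(NULL)
      v <- M[ok, hi + 1] - M[ok, lo + 1]; v[!is.finite(v)] <- 0
      v
    }
    lvl_key <- function(var, shift) {
      if (spec$collapse) sprintf("L.%s.D%d", var, shift)
      else sprintf("L.%s.D%d.t%d", var, shift, tt)
    }
    v <- lag_diff(spec$dependent, Y, 1L)
    if (!is.null(v))
      add_z(cid, lvl_key(spec$dependent, 1L), v,
            data.frame(part = "levels", variable = spec$dependent, lag = 1L,
                       period = if (spec$collapse) NA_integer_ else tt,
                       type = "gmm", stringsAsFactors = FALSE))
    for (r in spec$predetermined) {
      v <- lag_diff(r, Xw[[r]], 0L)
      if (!is.null(v))
        add_z(cid, lvl_key(r, 0L), v,
              data.frame(part = "levels", variable = r, lag = 0L,
                         period = if (spec$collapse) NA_integer_ else tt,
                         type = "gmm", stringsAsFactors = FALSE))
    }
    for (r in spec$endogenous) {
      v <- lag_diff(r, Xw[[r]], 1L)
      if (!is.null(v))
        add_z(cid, lvl_key(r, 1L), v,
              data.frame(part = "levels", variable = r, lag = 1L,
                         period = if (spec$collapse) NA_integer_ else tt,
                         type = "gmm", stringsAsFactors = FALSE))
    }
    for (r in spec$exogenous) {
      v <- Xw[[r]][ok, tt + 1]; v[!is.finite(v)] <- 0
      add_z(cid, sprintf("L.%s.iv", r), v,
            data.frame(part = "levels", variable = r, lag = 0L,
                       period = NA_integer_, type = "iv",
                       stringsAsFactors = FALSE))
    }
    add_z(cid, "L.constant", rep(1, length(ok)),
          data.frame(part = "levels", variable = "constant", lag = 0L,
                     period = NA_integer_, type = "iv",
                     stringsAsFactors = FALSE))
  }

  rowdf <- do.call(rbind, rows)
  chunk_ids <- rep(names(rows), vapply(rows, nrow, integer(1)))
  nrow_tot <- nrow(rowdf)
  ## assemble Z from per-chunk pieces
  Z <- matrix(0, nrow_tot, length(zvals),
              dimnames = list(NULL, names(zvals)))
  offsets <- c(0L, cumsum(vapply(rows, nrow, integer(1))))
  names(offsets) <- c(names(rows), "end")
  for (ci in names(zvals))
    for (cid in names(zvals[[ci]])) {
      o <- offsets[[cid]]
      Z[(o + 1):(o + length(zvals[[ci]][[cid]])), ci] <- zvals[[ci]][[cid]]
    }
  ## drop identically-zero columns (e.g. differences of time-invariant vars)
  nz <- colSums(Z != 0) > 0
  Z <- Z[, nz, drop = FALSE]
  cols <- do.call(rbind, colmeta[colnames(Z)])
  list(y = unlist(yrows, use.names = FALSE),
       X = do.call(rbind, Xrows),
       Z = Z, rows = rowdf, cols = cols,
       k = k, maxlag = maxlag)
}

## Moore-Penrose inverse via SVD (weighting matrices may be rank-deficient)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) stop("singular weighting matrix: the instrument set is ",
                       "fully collinear", call. = FALSE)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

sig_star <- function(p) {
  ifelse(p < 0.01, "1%", ifelse(p < 0.05, "5%", ifelse(p < 0.10, "10%", "ns")))
}

#' Fit a dynamic risk-factor equation by system GMM
#'
#' Blundell-Bond system GMM on an unbalanced long-format patient panel,
#' with two-step weighting and Windmeijer-corrected standard errors by
#' default, the Hansen test of overidentifying restrictions, and
#' Arellano-Bond AR(1)/AR(2) tests on the first-differenced residuals.
#'
#' @param panel Long panel data frame; see [build_instruments()].
#' @param spec A [model_spec()] or [ndr_model_spec()].
#' @return An object of class `dpm_gmm` with components `coefficients`,
#'   `se`, `vcov`, `stars`, `hansen`, `ar` (orders 1 and 2), `n_patients`,
#'   `person_years`, `n_instruments`, and the design bookkeeping.
#' @examples
#' \donttest{
#' pars <- cohort_params(n = 300, seed = 1)
#' panel <- generate_cohort(pars)
#' fit <- dpm_gmm(panel, ndr_model_spec("bmi", max_lag = 3))
#' summary(fit)
#' }
#' @export
dpm_gmm <- function(panel, spec) {
  d <- build_instruments(panel, spec)
  y <- d$y; X <- d$X; Z <- d$Z
  k <- ncol(X); L <- ncol(Z)
  if (L < k)
    stop("under-identified: ", L, " instruments for ", k, " parameters",
         call. = FALSE)
  idf <- factor(d$rows$patient)
  is_diff <- d$rows$part == "diff"

  ## one-step weighting: tridiagonal block for the differenced equation,
  ## identity for the levels equation
  Zd <- Z[is_diff, , drop = FALSE]
  Zl <- Z[!is_diff, , drop = FALSE]
  key <- paste(d$rows$patient, d$rows$t)
  dkey <- key[is_diff]; dprev <- paste(d$rows$patient, d$rows$t - 1)[is_diff]
  pair <- match(dprev, dkey)            # consecutive differenced rows
  has <- !is.na(pair)
  ZHZ <- 2 * crossprod(Zd) + crossprod(Zl)
  if (any(has)) {
    Cc <- crossprod(Zd[has, , drop = FALSE], Zd[pair[has], , drop = FALSE])
    ZHZ <- ZHZ - Cc - t(Cc)
  }
  W1 <- pinv(ZHZ)
  G <- crossprod(Z, X)
  Zy <- crossprod(Z, y)
  GW1 <- crossprod(G, W1)               # k x L
  A1 <- tryCatch(solve(GW1 %*% G), error = function(e)
    stop("singular weighting matrix: instruments are collinear with each ",
         "other or insufficient for the regressors", call. = FALSE))
  theta1 <- drop(A1 %*% (GW1 %*% Zy))
  names(theta1) <- colnames(X)
  u1 <- y - drop(X %*% theta1)
  M1 <- rowsum(Z * u1, idf)             # per-patient moment contributions
  S1 <- crossprod(M1)
  V1r <- A1 %*% (GW1 %*% S1 %*% t(GW1)) %*% A1  # robust one-step vcov

  if (spec$twostep) {
    W2 <- pinv(S1)
    GW2 <- crossprod(G, W2)
    A2 <- tryCatch(solve(GW2 %*% G), error = function(e)
      stop("singular two-step weighting matrix: reduce max_lag or collapse ",
           "the instruments", call. = FALSE))
    theta <- drop(A2 %*% (GW2 %*% Zy))
    names(theta) <- colnames(X)
    u <- y - drop(X %*% theta)
    g <- drop(crossprod(Z, u))
    ## Windmeijer finite-sample correction
    D <- matrix(0, k, k)
    W2g <- drop(W2 %*% g)
    for (j in seq_len(k)) {
      Mx <- rowsum(Z * X[, j], idf)
      Cj <- crossprod(Mx, M1)
      D[, j] <- drop(A2 %*% (GW2 %*% ((Cj + t(Cj)) %*% W2g)))
    }
    V <- A2 + D %*% A2 + A2 %*% t(D) + D %*% V1r %*% t(D)
    hansen_stat <- drop(crossprod(g, W2 %*% g))
    Amap <- A2 %*% GW2                  # k x L: theta-hat sensitivity to moments
  } else {
    theta <- theta1; u <- u1; V <- V1r
    g <- drop(crossprod(Z, u))
    W2 <- pinv(S1)
    hansen_stat <- drop(crossprod(g, W2 %*% g))
    Amap <- A1 %*% GW1
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(V), 0))
  zval <- theta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  df_h <- L - k
  hansen <- if (df_h > 0)
    list(statistic = hansen_stat, df = df_h,
         p.value = stats::pchisq(hansen_stat, df_h, lower.tail = FALSE))
  else NULL

  ## Arellano-Bond serial-correlation tests on differenced residuals
  e <- u[is_diff]
  Xd <- X[is_diff, , drop = FALSE]
  idd <- idf[is_diff]
  Mu <- rowsum(Z * u, idf)
  ar <- list()
  for (m in 1:2) {
    lagkey <- paste(d$rows$patient, d$rows$t - m)[is_diff]
    src <- match(lagkey, dkey)
    w <- ifelse(is.na(src), 0, e[src])
    if (sum(w != 0) == 0 || stats::sd(e) == 0) { ar[[m]] <- NULL; next }
    num <- sum(w * e)
    p_i <- rowsum(w * e, idd)
    term1 <- sum(p_i^2)
    if (term1 <= 0) { ar[[m]] <- NULL; next }
    q <- drop(crossprod(Xd, w))
    pid <- rowsum(w * e, idd)           # per-patient w'e, aligned to levels(idf)
    pfull <- setNames(rep(0, nlevels(idf)), levels(idf))
    pfull[rownames(pid)] <- pid[, 1]
    r <- drop(crossprod(Mu, pfull[rownames(Mu)]))
    term2 <- -2 * drop(crossprod(q, Amap %*% r))
    term3 <- drop(crossprod(q, V %*% q))
    denom <- term1 + term2 + term3
    if (!is.finite(denom) || denom <= 0) denom <- term1
    stat <- num / sqrt(denom)
    ar[[m]] <- list(order = m, statistic = stat,
                    p.value = 2 * stats::pnorm(-abs(stat)))
  }

  lvl <- d$rows[!is_diff, ]
  fit <- list(coefficients = theta, se = se, vcov = V,
              z = zval, p.value = pval, stars = sig_star(pval),
              onestep = theta1, hansen = hansen, ar = ar,
              n_patients = length(unique(d$rows$patient)),
              person_years = nrow(lvl),
              n_instruments = L, n_parameters = k,
              spec = spec, cols = d$cols,
              residuals = u, fitted = drop(X %*% theta),
              rows = d$rows)
  class(fit) <- "dpm_gmm"
  fit
}

#' @export
coef.dpm_gmm <- function(object, ...) object$coefficients

#' @export
vcov.dpm_gmm <- function(object, ...) object$vcov

#' @export
residuals.dpm_gmm <- function(object, ...) object$residuals

#' @export
fitted.dpm_gmm <- function(object, ...) object$fitted

#' @export
print.dpm_gmm <- function(x, ...) {
  cat("System GMM dynamic panel fit:", x$spec$dependent, "\n")
  cat(sprintf("  %d patients, %d person-years, %d instruments (%s, %s)\n",
              x$n_patients, x$person_years, x$n_instruments,
              if (x$spec$twostep) "two-step" else "one-step",
              if (x$spec$collapse) "collapsed" else "uncollapsed"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.dpm_gmm <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std.error = object$se,
                    z = object$z, p.value = object$p.value,
                    sig = object$stars)
  out <- list(table = tab, hansen = object$hansen, ar = object$ar,
              fit = object)
  class(out) <- "summary.dpm_gmm"
  out
}

#' @export
print.summary.dpm_gmm <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(cbind(round(x$table[, 1:4], 4), sig = x$table$sig))
  if (!is.null(x$hansen))
    cat(sprintf("\nHansen J = %.3f on %d df (p = %.3f)\n",
                x$hansen$statistic, x$hansen$df, x$hansen$p.value))
  for (a in x$ar)
    if (!is.null(a))
      cat(sprintf("AR(%d) z = %.3f (p = %.3f)\n", a$order, a$statistic,
                  a$p.value))
  invisible(x)
}

#' Hansen test of overidentifying restrictions
#'
#' @param fit A `dpm_gmm` object.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
hansen_test <- function(fit) {
  stopifnot(inherits(fit, "dpm_gmm"))
  if (is.null(fit$hansen))
    stop("Hansen test undefined: the model is just-identified (0 degrees ",
         "of freedom)", call. = FALSE)
  fit$hansen
}

#' Arellano-Bond serial-correlation test
#'
#' Tests for order-`order` autocorrelation in the first-differenced
#' residuals.  Order-1 rejection is expected by construction of the
#' differenced errors; order-2 rejection signals misspecification.
#'
#' @param fit A `dpm_gmm` object.
#' @param order 1 or 2.
#' @return List with `order`, `statistic`, `p.value`.
#' @export
ar_test <- function(fit, order = 1) {
  stopifnot(inherits(fit, "dpm_gmm"), order %in% 1:2)
  a <- if (length(fit$ar) >= order) fit$ar[[order]] else NULL
  if (is.null(a))
    stop("AR(", order, ") test undefined: too few periods or degenerate ",
         "residuals", call. = FALSE)
  a
}

#' Pooled least-squares comparator for a dynamic panel equation
#'
#' Fits the levels equation `y_t ~ y_{t-1} + x_t` by ordinary least squares,
#' pooling all patient-years and ignoring the patient-specific effect.  In a
#' dynamic model with patient heterogeneity this estimator is biased (the
#' lag coefficient is pushed upward); it is provided as the classical
#' benchmark against which the GMM estimator is judged.
#'
#' @param panel Long panel data frame.
#' @param spec A `dpm_spec` (classifications are ignored; only the regressor
#'   list matters).
#' @return List with `coefficients` (named as in [dpm_gmm()]) and `n`.
#' @export
pooled_ols <- function(panel, spec) {
  stopifnot(inherits(spec, "dpm_spec"))
  regs <- c(spec$exogenous, spec$predetermined, spec$endogenous)
  panel <- add_derived(panel, regs)
  panel <- panel[order(panel$patient_id, panel$duration), ]
  same <- c(FALSE, panel$patient_id[-1] == panel$patient_id[-nrow(panel)])
  consec <- same & c(FALSE, diff(panel$duration) == 1)
  idx <- which(consec)
  df <- data.frame(y = panel[[spec$dependent]][idx],
                   lag_y = panel[[spec$dependent]][idx - 1L])
  for (r in regs) df[[r]] <- panel[[r]][idx]
  df <- df[stats::complete.cases(df), ]
  f <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(f)
  names(cf)[names(cf) == "(Intercept)"] <- "constant"
  list(coefficients = cf, n = nrow(df), lm = f)
}
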