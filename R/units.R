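## Measurement conventions: HbA1c assay standards and the systolic-BP scale.

#' Convert HbA1c from the Swedish Mono-S standard to DCCT
#'
#' Swedish laboratories historically reported HbA1c on the HPLC Mono-S
#' standard; the equations in this package operate on the international
#' DCCT standard.  The two are related by the affine calibration
#' `DCCT = 0.923 * MonoS + 1.345` (both in %).
#'
#' @param value HbA1c in % on the Mono-S standard; must be positive.
#' @return HbA1c in % on the DCCT standard.
#' @examples
#' hba1c_monos_to_dcct(6.0)   # 6.883
#' @export
hba1c_monos_to_dcct <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("HbA1c (Mono-S) values must be positive and finite", call. = FALSE)
  0.923 * value + 1.345
}

#' Systolic blood pressure scale conversions
#'
#' The systolic-BP equation is estimated and iterated on a /10 scale
#' (138 mmHg enters the model as 13.8); public interfaces use mmHg.
#' `sbp_to_internal()` and `sbp_from_internal()` convert between the two and
#' are exact inverses.
#'
#' @param value Systolic BP in mmHg (`sbp_to_internal`) or in internal /10
#'   units (`sbp_from_internal`); must be positive.
#' @return The converted value.
#' @examples
#' sbp_to_internal(138)        # 13.8
#' sbp_from_internal(13.8)     # 138
#' @export
sbp_to_internal <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("systolic BP must be positive and finite", call. = FALSE)
  value / 10
}

#' @rdname sbp_to_internal
#' @export
sbp_from_internal <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("systolic BP must be positive and finite", call. = FALSE)
  value * 10
}

## internal: convert a public-unit value to an equation's modelling scale
to_internal <- function(eq, value) value / eq$scale
from_internal <- function(eq, value) value * eq$scale
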