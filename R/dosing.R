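# Allometric body-surface-area dosing.
#
# IV doses in the study design are prescribed as an intensity in mg per m2 of
# body surface area, with surface area estimated from body weight by the
# porcine allometric relation 0.0734 * weight^0.656 (m2 from kg). Computation
# keeps full precision throughout; rounding to one decimal happens only in the
# reporting layer, so downstream clearance estimates use the unrounded dose.

#' Constants of the allometric dose formula
#'
#' @param coefficient Multiplier in m2 per kg^`exponent`; default 0.0734.
#' @param exponent Allometric exponent (dimensionless); default 0.656.
#' @return A `dose_calc_params` list.
#' @export
dose_calc_params <- function(coefficient = 0.0734, exponent = 0.656) {
  if (!is.finite(coefficient) || coefficient <= 0 ||
      !is.finite(exponent) || exponent <= 0)
    stop("dose formula constants must be positive", call. = FALSE)
  structure(list(coefficient = coefficient, exponent = exponent),
            class = "dose_calc_params")
}

#' Body surface area from body weight
#'
#' `coefficient * weight_kg ^ exponent`, the allometric surface-area factor of
#' the dose formula.
#'
#' @param weight_kg Body weight in kg (> 0); vectorised.
#' @param params See [dose_calc_params()].
#' @return Surface area in m2, full precision.
#' @examples
#' body_surface_area(31)     # 0.6982... m2
#' @export
body_surface_area <- function(weight_kg, params = dose_calc_params()) {
  if (any(!is.finite(weight_kg) | weight_kg <= 0))
    stop("weight_kg must be positive", call. = FALSE)
  params$coefficient * weight_kg^params$exponent
}

#' Absolute dose from weight and dose intensity
#'
#' `body_surface_area(weight) * dose_per_m2_mg`. A 31.0 kg animal prescribed
#' 250 mg/m2 receives 174.6 mg (to the reported single decimal).
#'
#' @param weight_kg Body weight in kg (> 0); vectorised.
#' @param dose_per_m2_mg Dose intensity in mg/m2 (>= 0); vectorised.
#' @inheritParams body_surface_area
#' @return Absolute dose in mg, full precision.
#' @examples
#' compute_dose(31.0, 250)   # 174.57...
#' compute_dose(38.5, 350)   # 281.72...
#' @export
compute_dose <- function(weight_kg, dose_per_m2_mg,
                         params = dose_calc_params()) {
  if (any(!is.finite(dose_per_m2_mg) | dose_per_m2_mg < 0))
    stop("dose_per_m2_mg must be non-negative", call. = FALSE)
  body_surface_area(weight_kg, params) * dose_per_m2_mg
}
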