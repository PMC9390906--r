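#' Experimental (densitometer) dose uncertainty
#'
#' Propagates the densitometer reading uncertainty through the calibration
#' polynomial by the delta method: the dose uncertainty contributed by the
#' instrument is `|3a*OD^2 + 2b*OD + c| * delta_OD`, the local slope of the
#' calibration curve times the OD standard deviation. On a valid
#' (monotone) calibration domain the slope is positive; the absolute value
#' guards evaluation outside it.
#'
#' @param curve A `calibration_curve`.
#' @param od Optical density (vectorized, >= 0).
#' @param dens A [densitometer()] model supplying `delta_od`.
#' @return Dose uncertainty in cGy.
#' @examples
#' cal <- calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
#' experimental_uncertainty(cal, 0.1)
#' @export
experimental_uncertainty <- function(curve, od, dens = densitometer()) {
  stopifnot(inherits(curve, "calibration_curve"), inherits(dens, "densitometer"))
  if (!is.numeric(od) || any(od < 0)) {
    abort("`od` must be numeric and >= 0.", class = "filmdose_invalid_argument")
  }
  k <- curve$coefficients
  slope <- 3 * k[["a"]] * od^2 + 2 * k[["b"]] * od + k[["c"]]
  abs(slope) * dens$delta_od
}

#' Curve-fitting dose uncertainty
#'
#' Propagates the calibration-fit coefficient standard deviations into a
#' dose uncertainty at a given optical density:
#' `sqrt(sd_a^2*OD^6 + sd_b^2*OD^4 + sd_c^2*OD^2 + sd_d^2)`.
#'
#' @param curve A `calibration_curve` whose coefficient standard deviations
#'   are all present (a fitted curve, or one constructed with `sd=`).
#' @param od Optical density (vectorized, >= 0).
#' @return Dose uncertainty in cGy.
#' @export
fitting_uncertainty <- function(curve, od) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(od) || any(od < 0)) {
    abort("`od` must be numeric and >= 0.", class = "filmdose_invalid_argument")
  }
  s <- curve$coefficient_sd
  if (any(is.na(s))) {
    abort("Coefficient standard deviations are missing; fit the curve or supply `sd`.",
          class = "filmdose_configuration_error")
  }
  sqrt(s[["a"]]^2 * od^6 + s[["b"]]^2 * od^4 + s[["c"]]^2 * od^2 + s[["d"]]^2)
}

#' Combine uncertainty components in quadrature
#'
#' Total dose uncertainty from independent experimental and fitting
#' components: `sqrt(delta_e^2 + delta_f^2)`.
#'
#' @param delta_e Experimental dose uncertainty (cGy, >= 0; vectorized).
#' @param delta_f Fitting dose uncertainty (cGy, >= 0; vectorized).
#' @return Total dose uncertainty in cGy.
#' @examples
#' total_uncertainty(3, 4)
#' @export
total_uncertainty <- function(delta_e, delta_f) {
  if (!is.numeric(delta_e) || !is.numeric(delta_f) ||
      any(delta_e < 0) || any(delta_f < 0)) {
    abort("Uncertainty components must be numeric and >= 0.",
          class = "filmdose_invalid_argument")
  }
  sqrt(delta_e^2 + delta_f^2)
}

#' Per-dose uncertainty budget
#'
#' Evaluates the full uncertainty budget of a calibration curve at a set of
#' optical densities: dose, experimental component, fitting component,
#' quadrature total, and the total as a percentage of dose (reported only
#' where dose > 0).
#'
#' @param curve A fitted `calibration_curve` (coefficient SDs present).
#' @param od Optical densities at which to evaluate the budget.
#' @param dens A [densitometer()] model.
#' @return A tibble with columns `od`, `dose_cGy`, `delta_e_cGy`,
#'   `delta_f_cGy`, `delta_total_cGy`, `percent`.
#' @export
uncertainty_budget <- function(curve, od, dens = densitometer()) {
  dose <- od_to_dose(curve, od, strict = FALSE)
  de <- experimental_uncertainty(curve, od, dens)
  df <- fitting_uncertainty(curve, od)
  dt <- total_uncertainty(de, df)
  tibble::tibble(
    od = od,
    dose_cGy = dose,
    delta_e_cGy = de,
    delta_f_cGy = df,
    delta_total_cGy = dt,
    percent = ifelse(dose > 0, 100 * dt / dose, NA_real_)
  )
}
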