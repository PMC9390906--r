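#' Entrance dose calibration factor
#'
#' A film on the phantom surface does not read the dose at the depth of
#' maximum dose (Dmax, 0.5 cm for Co-60) that defines the entrance dose.
#' The entrance calibration factor is the ratio of the ionization-chamber
#' dose at Dmax to the surface film dose, both measured at reference
#' conditions: `Fcal_entrance = Ric / Rf`.
#'
#' @param ric Chamber dose at Dmax, reference conditions (cGy).
#' @param rf Film dose at the surface, reference conditions (cGy).
#' @return The dimensionless entrance calibration factor.
#' @examples
#' entrance_calibration_factor(200, 48.38)
#' @export
entrance_calibration_factor <- function(ric, rf) {
  check_scalar(ric, "ric", positive = TRUE)
  if (!is.numeric(rf) || length(rf) != 1 || !is.finite(rf) || rf <= 0) {
    abort("`rf` must be a single number > 0.", class = "filmdose_division_error")
  }
  ric / rf
}

#' Entrance dose from a surface film reading
#'
#' `D_entrance = Df * Fcal_entrance * prod(CF)`: the film dose scaled to
#' Dmax by the entrance calibration factor and adjusted for non-reference
#' irradiation conditions by the product of correction factors.
#'
#' @param df Film dose (cGy, >= 0; vectorized).
#' @param fcal_entrance Entrance dose calibration factor (> 0).
#' @param cf_product Product of correction factors (> 0; default 1,
#'   i.e. reference conditions).
#' @return Entrance dose in cGy.
#' @examples
#' entrance_dose(48.38, 4.134)
#' @export
entrance_dose <- function(df, fcal_entrance, cf_product = 1) {
  if (!is.numeric(df) || any(df < 0)) {
    abort("`df` must be numeric and >= 0.", class = "filmdose_invalid_argument")
  }
  check_scalar(fcal_entrance, "fcal_entrance", positive = TRUE)
  check_scalar(cf_product, "cf_product", positive = TRUE)
  df * fcal_entrance * cf_product
}

new_pdd_table <- function(knots, dmax_depth) {
  structure(list(knots = knots, dmax_depth = dmax_depth), class = "pdd_table")
}

#' Percentage-depth-dose table
#'
#' Depth-dose lookup for the beam: percent of the Dmax dose remaining at
#' each depth. PDD must be 100 at the depth of maximum dose (0.5 cm for
#' Co-60) and within (0, 100] at every knot.
#'
#' @param depth_cm Sorted depths in cm.
#' @param pdd_percent PDD values at those depths.
#' @param dmax_depth Depth of maximum dose in cm (default 0.5, Co-60).
#' @return A `pdd_table`.
#' @examples
#' pdd_table(c(0.5, 5, 10), c(100, 82.3, 62.5))
#' @export
pdd_table <- function(depth_cm, pdd_percent, dmax_depth = 0.5) {
  stopifnot(is.numeric(depth_cm), is.numeric(pdd_percent),
            length(depth_cm) == length(pdd_percent))
  if (is.unsorted(depth_cm, strictly = TRUE)) {
    abort("Depths must be strictly increasing.", class = "filmdose_invalid_argument")
  }
  if (any(pdd_percent <= 0) || any(pdd_percent > 100)) {
    abort("PDD values must be in (0, 100].", class = "filmdose_invalid_argument")
  }
  imax <- which(abs(depth_cm - dmax_depth) < 1e-9)
  if (length(imax) != 1 || abs(pdd_percent[imax] - 100) > 1e-9) {
    abort("PDD must be 100 at the depth of maximum dose.",
          class = "filmdose_invalid_argument")
  }
  new_pdd_table(tibble::tibble(depth_cm = depth_cm, pdd_percent = pdd_percent),
                dmax_depth)
}

#' @export
print.pdd_table <- function(x, ...) {
  cat(sprintf("<pdd_table> %d depths on [%g, %g] cm, Dmax at %g cm\n",
              nrow(x$knots), min(x$knots$depth_cm), max(x$knots$depth_cm),
              x$dmax_depth))
  invisible(x)
}

#' Dose at depth from the entrance dose and a PDD table
#'
#' `D(depth) = D_entrance * PDD(depth) / 100`, with PDD linearly
#' interpolated between tabulated depths. Depths outside the table raise a
#' range error.
#'
#' @param d_entrance Entrance dose (cGy).
#' @param table A [pdd_table()].
#' @param depth_cm Depth in cm (vectorized) within the table range.
#' @return Dose in cGy at the requested depth(s).
#' @export
dose_at_depth <- function(d_entrance, table, depth_cm) {
  check_scalar(d_entrance, "d_entrance", nonneg = TRUE)
  stopifnot(inherits(table, "pdd_table"))
  rng <- range(table$knots$depth_cm)
  if (any(depth_cm < rng[1] - 1e-9) || any(depth_cm > rng[2] + 1e-9)) {
    abort(sprintf("Depth outside PDD table range [%g, %g] cm.", rng[1], rng[2]),
          class = "filmdose_range_error")
  }
  pdd <- approx(table$knots$depth_cm, table$knots$pdd_percent,
                xout = depth_cm, method = "linear", rule = 1)$y
  d_entrance * pdd / 100
}

#' Extrapolate optical density to the skin reference depth
#'
#' The film's active layer sits at 0.080 mm, slightly deeper than the
#' 0.070 mm reference depth for skin dose. Given the OD read by a single
#' film (active layer at 0.080 mm) and by the bottom film of a four-film
#' stack (active layer at 0.935 mm), the OD at the target depth is found
#' by linear extrapolation in depth, solving the proportional relation
#' `(d2 - d1)/(d2 - target) = (od2 - od1)/(od2 - x)` for `x`.
#'
#' @param depth1_mm,od1 Depth (mm) and OD of the shallower measurement.
#' @param depth2_mm,od2 Depth (mm) and OD of the deeper measurement.
#' @param target_depth_mm Depth at which the OD is wanted (default 0.070).
#' @param precision Densitometer quantum used for the rounded value.
#' @return A list with `od_raw` (full precision) and `od_rounded`
#'   (densitometer precision).
#' @examples
#' extrapolate_od_to_depth(0.080, 0.03, 0.935, 0.08)
#' @export
extrapolate_od_to_depth <- function(depth1_mm, od1, depth2_mm, od2,
                                    target_depth_mm = 0.070,
                                    precision = 0.01) {
  for (nm in c("depth1_mm", "od1", "depth2_mm", "od2", "target_depth_mm")) {
    check_scalar(get(nm), nm)
  }
  if (abs(depth2_mm - depth1_mm) < 1e-12) {
    abort("The two depths must differ.", class = "filmdose_degenerate_geometry")
  }
  x <- od2 - (od2 - od1) * (depth2_mm - target_depth_mm) / (depth2_mm - depth1_mm)
  list(od_raw = x, od_rounded = quantize_od(x, precision))
}

#' Skin dose calibration factor
#'
#' Ratio of the film dose at the 0.070 mm skin reference depth to the film
#' dose at the 0.080 mm active-layer depth, each obtained by converting
#' the (extrapolated) optical density through the calibration curve. By
#' default the ODs are first rounded to densitometer precision, matching
#' how the ODs are read in practice; `round_od = FALSE` uses the raw
#' extrapolated values.
#'
#' @param od_at_target OD extrapolated to the skin reference depth.
#' @param od_at_layer OD at the film's active-layer depth.
#' @param curve A `calibration_curve`.
#' @param round_od Round both ODs to `precision` before converting.
#' @param precision Densitometer quantum.
#' @return The dimensionless skin calibration factor.
#' @examples
#' cal <- calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
#' skin_calibration_factor(0.0294, 0.03, cal)
#' @export
skin_calibration_factor <- function(od_at_target, od_at_layer, curve,
                                    round_od = TRUE, precision = 0.01) {
  check_scalar(od_at_target, "od_at_target", nonneg = TRUE)
  check_scalar(od_at_layer, "od_at_layer", nonneg = TRUE)
  stopifnot(inherits(curve, "calibration_curve"))
  if (round_od) {
    od_at_target <- quantize_od(od_at_target, precision)
    od_at_layer <- quantize_od(od_at_layer, precision)
  }
  num <- od_to_dose(curve, od_at_target, strict = FALSE)
  den <- od_to_dose(curve, od_at_layer, strict = FALSE)
  if (abs(den) < 1e-12) {
    abort("Film dose at the active-layer depth is zero.",
          class = "filmdose_division_error")
  }
  num / den
}

#' Skin dose from a film reading
#'
#' `D_skin = Df * Fcal_skin`: the surface film dose scaled to the
#' 0.070 mm skin reference depth.
#'
#' @param df Film dose (cGy, >= 0; vectorized).
#' @param fcal_skin Skin dose calibration factor (> 0; 1.00 at
#'   densitometer precision for this film geometry).
#' @return Skin dose in cGy.
#' @export
skin_dose <- function(df, fcal_skin = 1) {
  if (!is.numeric(df) || any(df < 0)) {
    abort("`df` must be numeric and >= 0.", class = "filmdose_invalid_argument")
  }
  check_scalar(fcal_skin, "fcal_skin", positive = TRUE)
  df * fcal_skin
}

#' Percent skin dose relative to the entrance dose
#'
#' Because both skin and entrance dose are proportional to the same film
#' reading, their ratio reduces to the calibration factors alone:
#' `% skin dose = 100 * Fcal_skin / (Fcal_entrance * prod(CF))`.
#'
#' @param fcal_entrance Entrance dose calibration factor (> 0).
#' @param cf_product Product of correction factors (> 0; 1 at reference).
#' @param fcal_skin Skin dose calibration factor (> 0).
#' @return Percent skin dose (full precision; round to integer for
#'   reporting).
#' @examples
#' percent_skin_dose(4.134)  # ~24% at reference conditions
#' @export
percent_skin_dose <- function(fcal_entrance, cf_product = 1, fcal_skin = 1) {
  check_scalar(fcal_entrance, "fcal_entrance", positive = TRUE)
  check_scalar(cf_product, "cf_product", positive = TRUE)
  check_scalar(fcal_skin, "fcal_skin", positive = TRUE)
  100 * fcal_skin / (fcal_entrance * cf_product)
}
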