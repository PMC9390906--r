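#' Pipeline run configuration
#'
#' Collects the fixed quantities a per-film dose report needs: the
#' prescription, the calibration factors, the densitometer model and the
#' rounding policy. Reference conditions are the standard 10 cm x 10 cm
#' open field at SSD 100 cm, gantry 0.
#'
#' @param prescribed_cGy Prescribed dose to Dmax (cGy, > 0).
#' @param fcal_entrance Entrance dose calibration factor.
#' @param fcal_skin Skin dose calibration factor.
#' @param dens A [densitometer()] model for the uncertainty budget.
#' @param skin_dose_digits Rounding for the reported percent skin dose
#'   (0 = integer, the conventional report).
#' @param deviation_digits Rounding for the reported percent deviation.
#' @param strict Enforce the calibration curve's OD domain.
#' @return A `run_config` object.
#' @export
run_config <- function(prescribed_cGy, fcal_entrance, fcal_skin = 1,
                       dens = densitometer(), skin_dose_digits = 0,
                       deviation_digits = 2, strict = TRUE) {
  check_scalar(prescribed_cGy, "prescribed_cGy", positive = TRUE)
  check_scalar(fcal_entrance, "fcal_entrance", positive = TRUE)
  check_scalar(fcal_skin, "fcal_skin", positive = TRUE)
  structure(list(prescribed_cGy = prescribed_cGy,
                 fcal_entrance = fcal_entrance, fcal_skin = fcal_skin,
                 dens = dens, skin_dose_digits = skin_dose_digits,
                 deviation_digits = deviation_digits, strict = strict,
                 reference = reference_conditions()),
            class = "run_config")
}

#' Run the full in vivo dosimetry pipeline over film readings
#'
#' For every film: net optical density, film dose through the calibration
#' curve, the per-dose uncertainty budget, the correction-factor product
#' for the film's irradiation conditions, entrance dose, skin dose,
#' percent skin dose, and percent deviation from the prescription. Raw
#' values are always emitted alongside the rounded report columns, so
#' every derived number is recomputable from the row itself.
#'
#' @param readings Tibble of film readings (`film_id`, `od_pre`,
#'   `od_post`, optional condition columns `field_size_cm`, `ssd_cm`,
#'   `gantry_deg`, `wedge_deg` with `NA` meaning at-reference).
#' @param curve A `calibration_curve`.
#' @param cfs A `cf_set` (or `NULL` if all films are at reference).
#' @param config A [run_config()].
#' @return A per-film report tibble.
#' @examples
#' cal <- ebt2_co60_curve()
#' readings <- tibble::tibble(film_id = "a", od_pre = 0, od_post = 0.05)
#' run_pipeline(readings, cal, NULL, run_config(200, 4.134))
#' @export
run_pipeline <- function(readings, curve, cfs = NULL, config) {
  stopifnot(inherits(curve, "calibration_curve"), inherits(config, "run_config"))
  if (!is.null(cfs)) stopifnot(inherits(cfs, "cf_set"))
  readings <- add_net_od(readings)
  cond_cols <- intersect(names(reference_conditions()), names(readings))

  cf_product <- purrr::pmap_dbl(
    readings[c(cond_cols, "film_id")],
    function(...) {
      vals <- c(...)
      film <- vals[["film_id"]]
      vals <- vals[names(vals) %in% cond_cols]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) return(1)
      if (is.null(cfs)) {
        abort(sprintf("Film %s has conditions but no cf_set was supplied [stage: correction].",
                      film),
              class = "filmdose_lookup_error")
      }
      suppressWarnings(storage.mode(vals) <- "double")
      tryCatch(product_cf(cfs, as.list(vals)),
               filmdose_lookup_error = function(e) {
                 abort(sprintf("Film %s: %s [stage: correction]", film,
                               conditionMessage(e)),
                       class = "filmdose_lookup_error")
               })
    })

  df_cGy <- od_to_dose(curve, readings$nod, strict = config$strict)
  delta_e <- experimental_uncertainty(curve, readings$nod, config$dens)
  # a curve built from published coefficients has no fit covariance;
  # report the experimental component alone in that case
  delta_f <- tryCatch(
    fitting_uncertainty(curve, readings$nod),
    filmdose_configuration_error = function(e) rep(NA_real_, nrow(readings))
  )
  delta_tot <- ifelse(is.na(delta_f), delta_e,
                      total_uncertainty(delta_e, dplyr::coalesce(delta_f, 0)))
  d_entrance <- df_cGy * config$fcal_entrance * cf_product
  d_skin <- df_cGy * config$fcal_skin
  pct_skin <- 100 * d_skin / d_entrance
  pct_dev <- 100 * abs(d_entrance - config$prescribed_cGy) / config$prescribed_cGy

  tibble::tibble(
    film_id = readings$film_id,
    nod = readings$nod,
    df_cGy = df_cGy,
    delta_e_cGy = delta_e,
    delta_f_cGy = delta_f,
    delta_total_cGy = delta_tot,
    cf_product = cf_product,
    d_entrance_cGy = d_entrance,
    d_skin_cGy = d_skin,
    percent_skin_raw = pct_skin,
    percent_skin = round(pct_skin, config$skin_dose_digits),
    prescribed_cGy = config$prescribed_cGy,
    percent_deviation_raw = pct_dev,
    percent_deviation = round(pct_dev, config$deviation_digits)
  )
}

#' @param report A pipeline report tibble.
#' @param path File path.
#' @rdname run_pipeline
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}
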