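# CSV dialects used by the pipeline. Every reader checks its schema and
# names the offending column; every writer round-trips through its reader.

read_checked_csv <- function(path, required, numeric_cols) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("File '%s' is missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")),
          class = "filmdose_schema_error")
  }
  for (col in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      abort(sprintf("Column '%s' in '%s' is not numeric (first bad row: %s).",
                    col, path, if (length(bad)) bad[1] else "?"),
            class = "filmdose_parse_error")
    }
  }
  df
}

#' Read and write film readings
#'
#' Film readings CSV: columns `film_id`, `od_pre`, `od_post`,
#' `encapsulated`; extra columns (e.g. condition columns) are preserved.
#' With `instrument_precision` set, ODs are snapped to the densitometer
#' quantum on read, as a physical readout cannot carry more resolution
#' than the display.
#'
#' @param path File path.
#' @param instrument_precision Densitometer quantum to snap ODs to on
#'   read, or `NULL` (default) to keep values as written.
#' @return A tibble of film readings.
#' @export
read_film_readings <- function(path, instrument_precision = NULL) {
  df <- read_checked_csv(path,
                         required = c("film_id", "od_pre", "od_post"),
                         numeric_cols = c("od_pre", "od_post"))
  if (!"encapsulated" %in% names(df)) df$encapsulated <- FALSE
  if (!is.null(instrument_precision)) {
    df$od_pre <- quantize_od(df$od_pre, instrument_precision)
    df$od_post <- quantize_od(df$od_post, instrument_precision)
  }
  df
}

#' @param readings Tibble of film readings.
#' @rdname read_film_readings
#' @export
write_film_readings <- function(readings, path) {
  readr::write_csv(readings, path)
  invisible(path)
}

#' Read and write calibration points
#'
#' Calibration CSV: columns `nod`, `dose_cGy`.
#'
#' @param path File path.
#' @return A tibble of calibration points.
#' @export
read_calibration_points <- function(path) {
  read_checked_csv(path, required = c("nod", "dose_cGy"),
                   numeric_cols = c("nod", "dose_cGy"))
}

#' @param points Tibble with `nod` and `dose_cGy`.
#' @rdname read_calibration_points
#' @export
write_calibration_points <- function(points, path) {
  readr::write_csv(points, path)
  invisible(path)
}

#' Read and write correction-factor measurements
#'
#' CF measurement CSV: columns `parameter`, `value`, `ric_cGy`, `rf_cGy`
#' (one row per paired chamber/film measurement).
#'
#' @param path File path.
#' @return A tibble of paired measurements.
#' @export
read_cf_measurements <- function(path) {
  read_checked_csv(path,
                   required = c("parameter", "value", "ric_cGy", "rf_cGy"),
                   numeric_cols = c("value", "ric_cGy", "rf_cGy"))
}

#' @param measurements Tibble of CF measurements.
#' @rdname read_cf_measurements
#' @export
write_cf_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read and write correction-factor tables
#'
#' CF table CSV: columns `parameter`, `value`, `cf`, `reference_value`.
#' A file may hold several parameters; reading returns a `cf_set`.
#'
#' @param path File path.
#' @return A `cf_set`.
#' @export
read_cf_set <- function(path) {
  df <- read_checked_csv(path,
                         required = c("parameter", "value", "cf",
                                      "reference_value"),
                         numeric_cols = c("value", "cf", "reference_value"))
  tables <- df |>
    dplyr::group_split(.data$parameter) |>
    purrr::map(function(d) {
      d <- dplyr::arrange(d, .data$value)
      cf_table(d$parameter[1], d$value, d$cf, d$reference_value[1])
    })
  cf_set(tables)
}

#' @param set A `cf_set`.
#' @rdname read_cf_set
#' @export
write_cf_set <- function(set, path) {
  stopifnot(inherits(set, "cf_set"))
  df <- purrr::map(unclass(set), function(t) {
    dplyr::mutate(t$knots, parameter = t$parameter,
                  reference_value = t$reference_value)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("parameter", "value", "cf", "reference_value")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read and write percentage-depth-dose tables
#'
#' PDD CSV: columns `depth_cm`, `pdd_percent`. A representative Co-60
#' 10 cm x 10 cm SSD-100 table (illustrative values, not measured data)
#' ships with the package:
#' `system.file("extdata", "pdd_co60_synthetic.csv", package = "filmdose")`.
#'
#' @param path File path.
#' @param dmax_depth Depth of maximum dose (cm).
#' @return A `pdd_table`.
#' @export
read_pdd_table <- function(path, dmax_depth = 0.5) {
  df <- read_checked_csv(path, required = c("depth_cm", "pdd_percent"),
                         numeric_cols = c("depth_cm", "pdd_percent"))
  df <- dplyr::arrange(df, .data$depth_cm)
  pdd_table(df$depth_cm, df$pdd_percent, dmax_depth = dmax_depth)
}

#' @param table A `pdd_table`.
#' @rdname read_pdd_table
#' @export
write_pdd_table <- function(table, path) {
  stopifnot(inherits(table, "pdd_table"))
  readr::write_csv(table$knots, path)
  invisible(path)
}

#' Serialize a calibration curve to JSON and back
#'
#' Stores coefficients, their standard deviations, the valid OD domain and
#' the fit correlation; full double precision is retained.
#'
#' @param curve A `calibration_curve`.
#' @param path File path for the JSON document.
#' @return `read_calibration_curve()` returns a `calibration_curve`.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(
    coefficients = as.list(curve$coefficients),
    coefficient_sd = as.list(curve$coefficient_sd),
    od_domain = curve$od_domain,
    r_fit = curve$r_fit,
    n_points = curve$n_points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration_curve
#' @export
read_calibration_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sds <- unlist(obj$coefficient_sd)
  sds <- sds[!is.na(sds)]
  curve <- calibration_curve(
    a = obj$coefficients$a, b = obj$coefficients$b,
    c = obj$coefficients$c, d = obj$coefficients$d,
    sd = if (length(sds) > 0) sds,
    od_domain = obj$od_domain,
    r_fit = obj$r_fit %||% NA_real_
  )
  curve$n_points <- obj$n_points %||% NA_integer_
  curve
}
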