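#' Correction factor from paired chamber/film readings
#'
#' A film's surface response drifts with irradiation conditions (electron
#' contamination grows with field size and gantry angle, beam hardening by
#' a wedge suppresses it). A correction factor normalizes the chamber-to-
#' film dose ratio at a clinical condition by the same ratio at the
#' reference condition (10 cm x 10 cm open field, SSD 100 cm, gantry 0):
#' `CF = (Ric/Rf)_clinical / (Ric/Rf)_reference`.
#'
#' @param ric_clinical,rf_clinical Ionization-chamber and film doses (cGy)
#'   at the clinical condition.
#' @param ric_reference,rf_reference The same pair at reference conditions.
#' @param condition Optional label used in error messages.
#' @return The dimensionless correction factor.
#' @examples
#' correction_factor(200, 96.76, 200, 48.38)
#' @export
correction_factor <- function(ric_clinical, rf_clinical,
                              ric_reference, rf_reference,
                              condition = NULL) {
  vals <- c(ric_clinical, rf_clinical, ric_reference, rf_reference)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort(paste0("All four readings must be finite and > 0",
                 if (!is.null(condition)) paste0(" (condition: ", condition, ")"),
                 "."),
          class = "filmdose_division_error")
  }
  (ric_clinical / rf_clinical) / (ric_reference / rf_reference)
}

new_cf_table <- function(parameter, knots, reference_value) {
  structure(list(parameter = parameter, knots = knots,
                 reference_value = reference_value),
            class = "cf_table")
}

cf_parameters <- c("field_size_cm", "ssd_cm", "gantry_deg", "wedge_deg")

#' Build a correction-factor table from paired measurements
#'
#' Takes chamber/film dose pairs measured while one irradiation parameter
#' was varied (all others at reference), normalizes each pair by the pair
#' at the reference value, and returns a lookup table of correction
#' factors keyed by the parameter value. The reference knot has CF = 1 by
#' construction.
#'
#' @param measurements Data frame with columns `value` (parameter setting),
#'   `ric_cGy` and `rf_cGy`; one row per setting, including the reference.
#' @param parameter One of `"field_size_cm"`, `"ssd_cm"`, `"gantry_deg"`,
#'   `"wedge_deg"`.
#' @param reference_value Parameter value at reference conditions
#'   (10, 100, 0, and 0 respectively). Must appear in `measurements$value`.
#' @return A `cf_table` with sorted `(value, cf)` knots.
#' @examples
#' m <- tibble::tibble(value = c(5, 10, 20),
#'                     ric_cGy = 200, rf_cGy = c(47, 48.38, 52))
#' build_cf_table(m, "field_size_cm", reference_value = 10)
#' @export
build_cf_table <- function(measurements, parameter, reference_value) {
  parameter <- match.arg(parameter, cf_parameters)
  if (!all(c("value", "ric_cGy", "rf_cGy") %in% names(measurements))) {
    abort("`measurements` needs `value`, `ric_cGy`, `rf_cGy` columns.",
          class = "filmdose_schema_error")
  }
  m <- dplyr::arrange(tibble::as_tibble(measurements), .data$value)
  if (any(duplicated(m$value))) {
    abort("Duplicate parameter values in CF measurements.",
          class = "filmdose_invalid_argument")
  }
  iref <- which(abs(m$value - reference_value) < 1e-9)
  if (length(iref) != 1) {
    abort(sprintf("Reference value %g not present in the measurements.",
                  reference_value),
          class = "filmdose_invalid_argument")
  }
  cf <- purrr::map2_dbl(m$ric_cGy, m$rf_cGy, function(ric, rf) {
    correction_factor(ric, rf, m$ric_cGy[iref], m$rf_cGy[iref],
                      condition = parameter)
  })
  knots <- tibble::tibble(value = m$value, cf = cf)
  new_cf_table(parameter, knots, reference_value)
}

#' Construct a correction-factor table directly from known factors
#'
#' For ground-truth tables or published factors, bypassing the paired
#' readings. The knot at `reference_value` must have CF = 1.
#'
#' @param parameter Parameter name, see [build_cf_table()].
#' @param values Sorted parameter settings.
#' @param cf Correction factors at `values` (all > 0).
#' @param reference_value Parameter value at reference conditions.
#' @return A `cf_table`.
#' @export
cf_table <- function(parameter, values, cf, reference_value) {
  parameter <- match.arg(parameter, cf_parameters)
  stopifnot(length(values) == length(cf), !is.unsorted(values, strictly = TRUE))
  if (any(cf <= 0)) {
    abort("Correction factors must be > 0.", class = "filmdose_invalid_argument")
  }
  iref <- which(abs(values - reference_value) < 1e-9)
  if (length(iref) != 1 || abs(cf[iref] - 1) > 1e-9) {
    abort("CF at the reference value must be present and equal 1.",
          class = "filmdose_invalid_argument")
  }
  new_cf_table(parameter, tibble::tibble(value = values, cf = cf),
               reference_value)
}

#' @export
print.cf_table <- function(x, ...) {
  cat(sprintf("<cf_table> %s (reference %g), %d knots on [%g, %g]\n",
              x$parameter, x$reference_value, nrow(x$knots),
              min(x$knots$value), max(x$knots$value)))
  print(x$knots, n = 6)
  invisible(x)
}

#' Interpolate a correction factor at a parameter value
#'
#' Piecewise-linear interpolation between the measured knots; exact at the
#' knots. Correction factors were measured on a grid and nothing is known
#' about behavior outside it, so extrapolation raises an error rather than
#' guessing.
#'
#' @param table A `cf_table`.
#' @param value Parameter value (vectorized) within the knot range.
#' @return Interpolated correction factor(s).
#' @export
lookup_cf <- function(table, value) {
  stopifnot(inherits(table, "cf_table"))
  rng <- range(table$knots$value)
  if (any(value < rng[1] - 1e-9) || any(value > rng[2] + 1e-9)) {
    abort(sprintf("%s = %s outside measured range [%g, %g]; refusing to extrapolate.",
                  table$parameter,
                  paste(value[value < rng[1] | value > rng[2]], collapse = ", "),
                  rng[1], rng[2]),
          class = "filmdose_extrapolation_error")
  }
  approx(table$knots$value, table$knots$cf, xout = value,
         method = "linear", rule = 1)$y
}

#' Bundle correction-factor tables into a set
#'
#' @param ... `cf_table` objects (at most one per parameter).
#' @return A `cf_set` keyed by parameter name.
#' @export
cf_set <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "cf_table")) {
    tables <- tables[[1]]
  }
  ok <- vapply(tables, inherits, logical(1), "cf_table")
  if (!all(ok)) abort("All elements must be cf_table objects.",
                      class = "filmdose_invalid_argument")
  nms <- vapply(tables, function(t) t$parameter, character(1))
  if (any(duplicated(nms))) {
    abort("Duplicate parameter tables in the set.",
          class = "filmdose_invalid_argument")
  }
  structure(setNames(tables, nms), class = "cf_set")
}

#' @export
print.cf_set <- function(x, ...) {
  cat(sprintf("<cf_set> parameters: %s\n",
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Product of correction factors for a set of irradiation conditions
#'
#' Looks up each named condition in its table and multiplies the factors.
#' Parameters without a stated condition contribute factor 1 (they are at
#' reference), as does an empty condition list.
#'
#' @param set A `cf_set`.
#' @param conditions Named list or named numeric vector of parameter
#'   values, e.g. `list(field_size_cm = 15, gantry_deg = 30)`.
#' @return The product of the individual correction factors.
#' @export
product_cf <- function(set, conditions = list()) {
  stopifnot(inherits(set, "cf_set"))
  conditions <- as.list(conditions)
  if (length(conditions) == 0) return(1)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    abort("`conditions` must be fully named.", class = "filmdose_invalid_argument")
  }
  missing <- setdiff(names(conditions), names(set))
  if (length(missing) > 0) {
    abort(sprintf("No correction-factor table for: %s.",
                  paste(missing, collapse = ", ")),
          class = "filmdose_lookup_error")
  }
  factors <- purrr::imap_dbl(conditions,
                             function(v, p) lookup_cf(set[[p]], v))
  prod(factors)
}

#' Compare film-configuration responses with a paired test
#'
#' Two-sided paired t-test of matched normalized responses from two film
#' configurations (e.g. unencapsulated vs encapsulated across the same
#' irradiation settings). The protocol fixes only the significance level;
#' a paired t-test on the matched series is used and recorded in the
#' output.
#'
#' @param series_a,series_b Numeric vectors of normalized responses,
#'   matched element-by-element when `paired = TRUE`.
#' @param paired Compare as matched pairs (default) or independent groups.
#' @param alpha Significance level for the reported decision.
#' @return A one-row tibble: `statistic`, `p_value`, `n`,
#'   `mean_difference`, `significant`, `method`.
#' @export
compare_configurations <- function(series_a, series_b, paired = TRUE,
                                   alpha = 0.05) {
  if (!is.numeric(series_a) || !is.numeric(series_b)) {
    abort("Both series must be numeric.", class = "filmdose_invalid_argument")
  }
  if (paired && length(series_a) != length(series_b)) {
    abort("Paired series must have equal lengths.", class = "filmdose_shape_error")
  }
  n <- length(series_a)
  if (n < 3 || (!paired && length(series_b) < 3)) {
    abort("Need at least 3 observations per series.",
          class = "filmdose_insufficient_data")
  }
  if (paired) {
    diffs <- series_a - series_b
    if (all(abs(diffs - mean(diffs)) < 1e-15)) {
      # zero within-pair variance: identical shift (or identical series)
      stat <- if (abs(mean(diffs)) < 1e-15) 0 else Inf
      p <- if (abs(mean(diffs)) < 1e-15) 1 else 0
      return(tibble::tibble(statistic = stat, p_value = p, n = n,
                            mean_difference = mean(diffs),
                            significant = p < alpha,
                            method = "paired t-test (two-sided)"))
    }
    ht <- t.test(series_a, series_b, paired = TRUE)
    method <- "paired t-test (two-sided)"
  } else {
    ht <- t.test(series_a, series_b, paired = FALSE)
    method <- "Welch t-test (two-sided)"
  }
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = n,
    mean_difference = unname(if (paired) ht$estimate else diff(rev(ht$estimate))),
    significant = ht$p.value < alpha,
    method = method
  )
}
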