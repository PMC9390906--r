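#' Net optical density of an irradiated film
#'
#' The dose signal of a radiochromic film is the change in optical density
#' caused by irradiation: the post-irradiation reading minus the
#' pre-irradiation (background) reading, NOD = OD2 - OD1.
#'
#' Negative net optical densities are physically suspect (the film cannot
#' lighten under irradiation) but can arise from readout noise at very low
#' dose; they are returned as-is with a warning rather than clamped.
#'
#' @param od_pre Optical density before irradiation (OD1). Vectorized.
#' @param od_post Optical density after irradiation (OD2). Vectorized.
#' @return Numeric vector of net optical densities.
#' @examples
#' net_optical_density(0.03, 0.08)
#' @export
net_optical_density <- function(od_pre, od_post) {
  if (!is.numeric(od_pre) || !is.numeric(od_post)) {
    abort("Optical densities must be numeric.", class = "filmdose_invalid_reading")
  }
  if (any(od_pre < 0, na.rm = TRUE) || any(od_post < 0, na.rm = TRUE)) {
    abort("Optical densities must be >= 0.", class = "filmdose_invalid_reading")
  }
  nod <- od_post - od_pre
  if (any(nod < 0, na.rm = TRUE)) {
    warn(sprintf("%d net optical density value(s) are negative.", sum(nod < 0, na.rm = TRUE)),
         class = "filmdose_negative_nod")
  }
  nod
}

#' Add net optical density to a tibble of film readings
#'
#' Data-frame-first companion to [net_optical_density()]: takes a readings
#' table with `od_pre` and `od_post` columns and appends a `nod` column.
#'
#' @param readings Data frame with numeric `od_pre` and `od_post` columns.
#' @return A tibble with a `nod` column appended.
#' @examples
#' add_net_od(tibble::tibble(film_id = "f1", od_pre = 0.03, od_post = 0.08))
#' @export
add_net_od <- function(readings) {
  if (!all(c("od_pre", "od_post") %in% names(readings))) {
    abort("`readings` needs `od_pre` and `od_post` columns.",
          class = "filmdose_schema_error")
  }
  dplyr::mutate(tibble::as_tibble(readings),
                nod = net_optical_density(.data$od_pre, .data$od_post))
}

new_calibration_curve <- function(coefficients, coefficient_sd, od_domain,
                                  r_fit, n_points = NA_integer_, fit = NULL) {
  structure(
    list(
      coefficients = coefficients,      # named c(a, b, c, d), dose = a*od^3 + ... + d
      coefficient_sd = coefficient_sd,  # named like coefficients; may be NA
      od_domain = od_domain,            # c(lo, hi)
      r_fit = r_fit,
      n_points = n_points,
      fit = fit
    ),
    class = "calibration_curve"
  )
}

#' Construct a cubic film calibration curve from known coefficients
#'
#' Builds the dose-response model `dose = a*OD^3 + b*OD^2 + c*OD + d`
#' (dose in cGy, OD the net optical density) directly from its
#' coefficients, e.g. a published calibration. The curve must be strictly
#' increasing on `od_domain`; this is checked on a 1000-point grid at
#' construction.
#'
#' @param a,b,c,d Polynomial coefficients (cGy per OD^3, OD^2, OD, and cGy).
#' @param sd Optional named numeric vector of coefficient standard
#'   deviations, names among `a`, `b`, `c`, `d`; missing entries are `NA`.
#' @param od_domain Closed interval of optical densities over which the
#'   curve is valid; lower bound must be >= 0.
#' @param r_fit Correlation between measured and fitted dose, if known.
#' @return A `calibration_curve` object.
#' @examples
#' calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
#' @export
calibration_curve <- function(a, b, c, d, sd = NULL, od_domain = c(0, 1),
                              r_fit = NA_real_) {
  for (nm in c("a", "b", "c", "d")) check_scalar(get(nm), nm)
  if (!is.numeric(od_domain) || length(od_domain) != 2 ||
      od_domain[1] < 0 || od_domain[2] <= od_domain[1]) {
    abort("`od_domain` must be an increasing interval with lower bound >= 0.",
          class = "filmdose_invalid_argument")
  }
  coefs <- c(a = a, b = b, c = c, d = d)
  sds <- c(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_)
  if (!is.null(sd)) {
    if (is.null(names(sd)) || !all(names(sd) %in% names(sds))) {
      abort("`sd` must be named with a subset of a, b, c, d.",
            class = "filmdose_invalid_argument")
    }
    sds[names(sd)] <- sd
  }
  curve <- new_calibration_curve(coefs, sds, od_domain, r_fit)
  assert_monotone(curve)
  curve
}

# strictly-increasing check on a uniform grid (sign of increments, tol 0)
assert_monotone <- function(curve, n_grid = 1000) {
  grid <- seq(curve$od_domain[1], curve$od_domain[2], length.out = n_grid)
  vals <- eval_curve(curve, grid)
  if (any(diff(vals) <= 0)) {
    abort("Calibration polynomial is not strictly increasing on its OD domain.",
          class = "filmdose_monotonicity_error")
  }
  invisible(curve)
}

eval_curve <- function(curve, od) {
  k <- curve$coefficients
  k[["a"]] * od^3 + k[["b"]] * od^2 + k[["c"]] * od + k[["d"]]
}

#' Fit the cubic dose-calibration curve to chamber-referenced points
#'
#' Fits `dose = a*NOD^3 + b*NOD^2 + c*NOD + d` by unweighted least squares
#' to calibration points whose absorbed doses were determined with an
#' ionization chamber. Coefficient standard deviations come from the fit
#' covariance, the fit correlation `r_fit` is the Pearson correlation
#' between observed and fitted doses, and the valid OD domain is the range
#' of the supplied net optical densities.
#'
#' @param points Data frame with numeric columns `nod` (net optical
#'   density) and `dose_cGy` (chamber dose, cGy); at least 5 rows with at
#'   least 4 distinct NOD values.
#' @return A `calibration_curve` with coefficients, their standard
#'   deviations, `od_domain`, and `r_fit`.
#' @seealso [od_to_dose()], [dose_to_od()], [tidy.calibration_curve()]
#' @examples
#' pts <- tibble::tibble(nod = seq(0.05, 0.6, length.out = 10))
#' pts$dose_cGy <- 1685 * pts$nod^3 - 187.9 * pts$nod^2 + 1006 * pts$nod - 2.328
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points) {
  if (!all(c("nod", "dose_cGy") %in% names(points))) {
    abort("`points` needs `nod` and `dose_cGy` columns.",
          class = "filmdose_schema_error")
  }
  points <- tibble::as_tibble(points)
  if (any(points$dose_cGy < 0)) {
    abort("Calibration doses must be >= 0.", class = "filmdose_invalid_argument")
  }
  if (nrow(points) < 5 || dplyr::n_distinct(points$nod) < 4) {
    abort("Need >= 5 calibration points with >= 4 distinct NOD values.",
          class = "filmdose_fit_error")
  }
  fit <- lm(dose_cGy ~ poly(nod, 3, raw = TRUE), data = points)
  beta <- unname(coef(fit))          # (Intercept), od, od^2, od^3
  # noiseless input makes summary.lm warn about a perfect fit; the
  # coefficient covariance (all zeros) is still what we want
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  coefs <- c(a = beta[4], b = beta[3], c = beta[2], d = beta[1])
  sds <- c(a = se[4], b = se[3], c = se[2], d = se[1])
  names(sds) <- names(coefs)
  r_fit <- cor(points$dose_cGy, fitted(fit))
  curve <- new_calibration_curve(coefs, sds,
                                 od_domain = range(points$nod),
                                 r_fit = r_fit, n_points = nrow(points),
                                 fit = fit)
  assert_monotone(curve)
  curve
}

#' Convert optical density to absorbed dose
#'
#' Evaluates the cubic calibration polynomial at the given net optical
#' densities. The raw polynomial value is returned, which can be slightly
#' negative near OD 0 (the fitted intercept is not constrained to zero);
#' use `clamp = TRUE` for reporting, which floors negative doses at zero
#' with a warning.
#'
#' @param curve A `calibration_curve`.
#' @param od Net optical density (vectorized).
#' @param strict If `TRUE` (default), ODs outside the curve's valid domain
#'   raise a domain error; if `FALSE` the polynomial is still evaluated.
#' @param clamp If `TRUE`, negative doses are reported as 0 with a warning.
#' @return Absorbed dose in cGy.
#' @examples
#' cal <- calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
#' od_to_dose(cal, 0.14)
#' @export
od_to_dose <- function(curve, od, strict = TRUE, clamp = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(od)) abort("`od` must be numeric.", class = "filmdose_invalid_argument")
  if (strict && (any(od < curve$od_domain[1] - 1e-12) ||
                 any(od > curve$od_domain[2] + 1e-12))) {
    abort(sprintf("OD outside calibration domain [%g, %g].",
                  curve$od_domain[1], curve$od_domain[2]),
          class = "filmdose_domain_error")
  }
  dose <- eval_curve(curve, od)
  if (clamp && any(dose < 0)) {
    warn(sprintf("%d dose value(s) were negative and clamped to 0.",
                 sum(dose < 0)),
         class = "filmdose_negative_dose")
    dose <- pmax(dose, 0)
  }
  dose
}

#' Invert the calibration curve: dose to optical density
#'
#' Finds the unique optical density at which the (strictly increasing)
#' calibration polynomial equals the requested dose, by root bisection to
#' an absolute dose tolerance of 1e-9 cGy. Needed by the synthetic-data
#' generator to turn ground-truth doses into film signals.
#'
#' @param curve A `calibration_curve`.
#' @param dose Absorbed dose in cGy (vectorized). Must lie within the range
#'   the curve attains on its OD domain.
#' @return Net optical density.
#' @examples
#' cal <- calibration_curve(1685, -187.9, 1006, -2.328, od_domain = c(0, 0.65))
#' dose_to_od(cal, 200)
#' @export
dose_to_od <- function(curve, dose) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(dose)) abort("`dose` must be numeric.", class = "filmdose_invalid_argument")
  lo <- curve$od_domain[1]; hi <- curve$od_domain[2]
  dmin <- eval_curve(curve, lo); dmax <- eval_curve(curve, hi)
  if (any(dose < dmin - 1e-9) || any(dose > dmax + 1e-9)) {
    abort(sprintf("Dose outside attainable range [%.4f, %.4f] cGy.", dmin, dmax),
          class = "filmdose_range_error")
  }
  vapply(dose, function(d) {
    if (d <= dmin) return(lo)
    if (d >= dmax) return(hi)
    uniroot(function(x) eval_curve(curve, x) - d, lower = lo, upper = hi,
            tol = .Machine$double.eps^0.9, maxiter = 2000)$root
  }, numeric(1))
}

#' @export
print.calibration_curve <- function(x, ...) {
  k <- x$coefficients
  cat("<calibration_curve>  dose [cGy] = a*OD^3 + b*OD^2 + c*OD + d\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g, d = %.6g\n",
              k[["a"]], k[["b"]], k[["c"]], k[["d"]]))
  if (!all(is.na(x$coefficient_sd))) {
    s <- x$coefficient_sd
    cat(sprintf("  sd: a %.3g, b %.3g, c %.3g, d %.3g\n",
                s[["a"]], s[["b"]], s[["c"]], s[["d"]]))
  }
  cat(sprintf("  OD domain [%g, %g]", x$od_domain[1], x$od_domain[2]))
  if (!is.na(x$r_fit)) cat(sprintf(", r_fit = %.4f", x$r_fit))
  cat("\n")
  invisible(x)
}
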