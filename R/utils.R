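#' Quantize optical densities to the densitometer readout precision
#'
#' Point densitometers report optical density on a display limited to two
#' decimal places, so every instrument reading is an integer multiple of
#' 0.01 OD. Derived quantities (net OD, extrapolated OD) keep full precision
#' unless explicitly quantized for reporting.
#'
#' @param od Numeric vector of optical densities.
#' @param precision Readout quantum in OD units (default 0.01).
#' @return `od` rounded to the nearest multiple of `precision`.
#' @examples
#' quantize_od(c(0.0294, 0.1957))
#' @export
quantize_od <- function(od, precision = 0.01) {
  stopifnot(is.numeric(od), is.numeric(precision), precision > 0)
  round(od / precision) * precision
}

#' Densitometer readout model
#'
#' Bundles the two numbers that characterize a point densitometer for the
#' uncertainty budget: the standard deviation attributed to a single OD
#' reading and the display quantum. Following common practice the readout
#' quantum itself (0.01 OD) is used as the reading standard deviation by
#' default.
#'
#' @param delta_od Standard deviation of one OD reading (OD units).
#' @param precision Display quantum (OD units).
#' @return An object of class `densitometer`.
#' @examples
#' densitometer()
#' @export
densitometer <- function(delta_od = 0.01, precision = 0.01) {
  stopifnot(is.numeric(delta_od), length(delta_od) == 1, delta_od >= 0)
  stopifnot(is.numeric(precision), length(precision) == 1, precision > 0)
  structure(list(delta_od = delta_od, precision = precision),
            class = "densitometer")
}

#' @export
print.densitometer <- function(x, ...) {
  cat(sprintf("<densitometer> delta_OD = %g, readout quantum = %g OD\n",
              x$delta_od, x$precision))
  invisible(x)
}

# shared argument check: scalar finite numeric
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "filmdose_invalid_argument")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name),
          class = "filmdose_invalid_argument")
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0.", name),
          class = "filmdose_invalid_argument")
  }
  invisible(x)
}
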