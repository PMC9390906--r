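#' Tidy a fitted calibration curve
#'
#' Returns one row per polynomial coefficient in descending power order
#' (`a` = cubic term through `d` = constant), with the standard deviation
#' from the fit covariance where available.
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$coefficient_sd)
  )
}

#' One-row summary of a fitted calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A tibble with `r_fit` (correlation between measured and fitted
#'   dose), `n_points`, and the OD domain bounds.
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    r_fit = x$r_fit,
    n_points = x$n_points,
    od_min = x$od_domain[1],
    od_max = x$od_domain[2]
  )
}

#' Plot a calibration curve and (if fitted) its calibration points
#'
#' @param object A `calibration_curve`.
#' @param n Number of evaluation points along the OD domain.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_curve <- function(object, n = 200, ...) {
  grid <- tibble::tibble(
    nod = seq(object$od_domain[1], object$od_domain[2], length.out = n)
  )
  grid$dose_cGy <- od_to_dose(object, grid$nod)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$nod, y = .data$dose_cGy)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::labs(x = "Net optical density", y = "Absorbed dose (cGy)",
                  title = "Film dose calibration")
  if (!is.null(object$fit)) {
    m <- object$fit$model
    pts <- tibble::tibble(dose_cGy = m[[1]], nod = m[[2]][, 1])
    p <- p + ggplot2::geom_point(data = pts, size = 2, colour = "grey25")
  }
  p
}
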