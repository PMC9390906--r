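#' Plot a per-dose uncertainty budget
#'
#' Total dose uncertainty (absolute or percent of dose) against absorbed
#' dose, with the experimental and fitting components overlaid.
#'
#' @param budget Output of [uncertainty_budget()].
#' @param percent Plot the percent-of-dose scale instead of cGy.
#' @return A ggplot object.
#' @export
plot_uncertainty_budget <- function(budget, percent = FALSE) {
  if (percent) {
    return(
      ggplot2::ggplot(budget, ggplot2::aes(x = .data$dose_cGy, y = .data$percent)) +
        ggplot2::geom_line(colour = "#b2182b") +
        ggplot2::geom_point(colour = "#b2182b") +
        ggplot2::labs(x = "Absorbed dose (cGy)",
                      y = "Total dose uncertainty (% of dose)")
    )
  }
  long <- budget |>
    dplyr::select("dose_cGy", "delta_e_cGy", "delta_f_cGy", "delta_total_cGy") |>
    tidyr::pivot_longer(-"dose_cGy", names_to = "component",
                        values_to = "uncertainty_cGy") |>
    dplyr::mutate(component = dplyr::recode(.data$component,
                                            delta_e_cGy = "experimental",
                                            delta_f_cGy = "fitting",
                                            delta_total_cGy = "total"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dose_cGy,
                                     y = .data$uncertainty_cGy,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Absorbed dose (cGy)", y = "Dose uncertainty (cGy)",
                  colour = NULL)
}

#' Plot normalized film responses across irradiation parameters
#'
#' One panel per irradiation parameter, unencapsulated and encapsulated
#' film overlaid — the visual counterpart of the correction-factor
#' tables.
#'
#' @param landscape Output of [generate_cf_landscape()] or measured data
#'   in the same layout.
#' @return A ggplot object.
#' @export
plot_normalized_response <- function(landscape) {
  nd <- normalized_response(landscape) |>
    dplyr::mutate(configuration = ifelse(.data$encapsulated,
                                         "encapsulated", "unencapsulated"))
  ggplot2::ggplot(nd, ggplot2::aes(x = .data$value,
                                   y = .data$normalized_response,
                                   colour = .data$configuration)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Parameter value", y = "Normalized response",
                  colour = NULL)
}

#' Plot correction-factor tables
#'
#' @param set A `cf_set`.
#' @return A ggplot object with one panel per parameter.
#' @export
plot_cf_set <- function(set) {
  stopifnot(inherits(set, "cf_set"))
  df <- purrr::map(unclass(set), function(t) {
    dplyr::mutate(t$knots, parameter = t$parameter)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cf)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac", size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Parameter value", y = "Correction factor")
}

#' Plot post-exposure optical-density growth series
#'
#' @param series A tibble from [generate_growth_series()], or several
#'   bound together with a `dose_cGy` column distinguishing them.
#' @return A ggplot object.
#' @export
plot_growth_series <- function(series) {
  aes <- if ("dose_cGy" %in% names(series)) {
    ggplot2::aes(x = .data$time_min, y = .data$od,
                 colour = factor(.data$dose_cGy))
  } else {
    ggplot2::aes(x = .data$time_min, y = .data$od)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time after exposure (min)", y = "Optical density",
                  colour = "Dose (cGy)")
}
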