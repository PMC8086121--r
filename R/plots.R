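#' Plot a road network
#'
#' @param object A `road_network`.
#' @param ... Unused.
#' @return A ggplot: edges coloured by road class.
#' @export
autoplot.road_network <- function(object, ...) {
  ggplot2::ggplot(object$edges) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$road_type)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "road class") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a GAMMAR fit
#'
#' Forest plot of the fixed-effect and MA estimates with 95% intervals.
#'
#' @param object A `gammar_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gammar_fit <- function(object, ...) {
  td <- tidy(object, effects = c("fixed", "ma")) %>%
    filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high,
                   colour = .data$effect)) +
    ggplot2::labs(x = "estimate (95% interval)", y = NULL,
                  title = paste("GAMMAR:", object$spec$response)) +
    ggplot2::theme_minimal()
}

#' Plot dose and intake accumulation curves
#'
#' Cumulative noise dose (% of criterion) and NO2 intake (µg) against
#' riding time, one panel per response and location, coloured by road
#' class, with the thresholds as horizontal lines.
#'
#' @param object A `dose_curves` tibble from [hazard_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_curves <- function(object, ...) {
  d <- filter(object,
              .data$response != "no2_intake_ug_pedestrian_threshold")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute, y = .data$value,
                                  colour = .data$road_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_grid(.data$response ~ .data$location_label,
                        scales = "free_y") +
    ggplot2::labs(x = "minutes of riding", y = "cumulative dose",
                  colour = "road class") +
    ggplot2::theme_minimal()
}
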