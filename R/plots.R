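#' Plot an accuracy time course
#'
#' Mean cross-validated accuracy with a fold-wise standard-error ribbon, the
#' 50% guessing rate, and (optionally) shaded significant intervals.
#'
#' @param object An `accuracy_timecourse`.
#' @param intervals Optional interval tibble from [extract_intervals()].
#' @param chance Chance rate to draw (default 0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_timecourse <- function(object, intervals = NULL,
                                         chance = 0.5, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms,
                                            y = .data$accuracy))
  if (!is.null(intervals) && nrow(intervals)) {
    p <- p + ggplot2::geom_rect(
      data = intervals, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "goldenrod", alpha = 0.25)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$se,
                                      ymax = .data$accuracy + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Time relative to target onset (ms)",
                  y = "Decoding accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a condition-difference topography
#'
#' Sensor-space map of the signed far-minus-near differences; significant
#' channels are outlined. Requires the head model for sensor coordinates
#' (top view: x right, y anterior).
#'
#' @param object A `topo_stats` tibble from [topo_difference()].
#' @param head The `head_model` the epochs were simulated with.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.topo_stats <- function(object, head, ...) {
  pos <- head$sensor_positions
  df <- dplyr::mutate(as_tibble(object),
                      x = pos[, 1], y = pos[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$diff_uv)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 4) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 21, `TRUE` = 23)) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "far - near (µV)", shape = "p < alpha",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a source estimate
#'
#' Source-space scatter (top view) colored by signed amplitude.
#'
#' @param object A `source_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.source_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$amplitude,
                                       size = abs(.data$amplitude))) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(low = "navy", mid = "grey85",
                                   high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::guides(size = "none") +
    ggplot2::labs(color = "amplitude", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
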