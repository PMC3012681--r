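#' Plot tracks in arena coordinates
#'
#' Draws each track as a colored path in pixel coordinates, with the y axis
#' reversed so the plot matches image orientation (row 0 at the top).
#'
#' @param tracks A `larva_tracks` tibble.
#' @param mm Plot in millimetres instead of pixels (uses the table's
#'   `mm_per_px`). Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, mm = FALSE) {
  df <- tibble::as_tibble(tracks)
  scale <- if (mm) attr(tracks, "mm_per_px") %||% 0.3 else 1
  unit <- if (mm) "mm" else "px"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * scale, y = .data$y * scale,
                                   group = .data$track_id,
                                   colour = factor(.data$track_id))) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")"),
                  colour = "track") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tracks
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.larva_tracks <- function(object, ...) plot_tracks(object, ...)

#' Plot a pooled speed distribution
#'
#' @param dist A `larva_speed_dist` tibble from [speed_distribution()].
#' @return A ggplot object; the pooled mean is drawn as a dashed line.
#' @export
plot_speed_distribution <- function(dist) {
  df <- tibble::as_tibble(dist)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2,
                                   y = .data$density)) +
    ggplot2::geom_col(width = attr(dist, "bin_width") %||% 0.1,
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(dist, "mean_speed"),
                        linetype = "dashed") +
    ggplot2::labs(x = "instantaneous speed (mm/s)", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname plot_speed_distribution
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.larva_speed_dist <- function(object, ...) plot_speed_distribution(object)

#' Plot per-frame detection counts of a method comparison
#'
#' @param comparison A `larva_comparison` from [run_compare()].
#' @return A ggplot object.
#' @export
plot_detection_counts <- function(comparison) {
  ggplot2::ggplot(comparison$counts,
                  ggplot2::aes(x = .data$frame, y = .data$n,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "objects above threshold",
                  colour = "method") +
    ggplot2::theme_minimal()
}
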