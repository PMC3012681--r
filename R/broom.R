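#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-track summaries
#'
#' One row per track: length, duration, net and total displacement, and
#' mean speed (from raw, unsmoothed steps).
#'
#' @param x A `larva_tracks` tibble.
#' @param ... Unused.
#' @return A tibble with one row per track.
#' @export
tidy.larva_tracks <- function(x, ...) {
  fps <- attr(x, "fps") %||% 3.75
  mm_per_px <- attr(x, "mm_per_px") %||% 0.3
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      first_frame = min(.data$frame),
      last_frame = max(.data$frame),
      duration_s = (dplyr::n() - 1) / fps,
      path_px = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      net_px = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                      (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_speed_mm_s = ifelse(
      .data$n_points > 1,
      .data$path_px / (.data$n_points - 1) * mm_per_px * fps,
      NA_real_))
}

#' Glance at a track set
#'
#' @param x A `larva_tracks` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of tracks, total points, mean and sd of
#'   track duration.
#' @export
glance.larva_tracks <- function(x, ...) {
  d <- track_durations(x)
  tibble::tibble(
    n_tracks = nrow(d),
    n_points = sum(d$n_points),
    duration_mean_s = if (nrow(d) > 0) mean(d$duration_s) else NaN,
    duration_sd_s = if (nrow(d) > 1) sd(d$duration_s) else NA_real_
  )
}

#' Glance at a speed distribution
#'
#' @param x A `larva_speed_dist`.
#' @param ... Unused.
#' @return A one-row tibble with pooled mean speed, sample size and bin
#'   width.
#' @export
glance.larva_speed_dist <- function(x, ...) {
  tibble::tibble(
    mean_speed_mm_s = attr(x, "mean_speed"),
    n = attr(x, "n"),
    bin_width = attr(x, "bin_width")
  )
}
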