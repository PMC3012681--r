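#' Link per-frame detections into tracks
#'
#' Greedy globally-nearest-first matching between the heads of active tracks
#' (their detection in the previous frame) and the detections of the current
#' frame. All candidate (head, detection) pairs are sorted by Euclidean
#' distance; pairs with distance strictly less than `link_max_px` are
#' accepted nearest first, each head and each detection used at most once.
#' Ties are broken by lower track id, then lower detection index, so linking
#' is deterministic. Unmatched detections start new tracks; a track with no
#' match in a frame is closed for good — there is no gap bridging, and a
#' reappearing animal starts a new track. Crossing animals may swap
#' identities; resolving track intersections is out of scope.
#'
#' @param detections A `larva_detections` tibble from [detect_blobs()], or
#'   any tibble with `frame`, `x`, `y` columns (0-based frame indices).
#' @param link_max_px Maximum joinable displacement in pixels; a jump of
#'   exactly `link_max_px` does **not** link. Default 10.
#' @return A `larva_tracks` tibble with columns `track_id`, `frame`, `x`,
#'   `y`; within a track, frame indices are consecutive and every step is
#'   shorter than `link_max_px`.
#' @examples
#' det <- tibble::tibble(frame = 0:4, x = 2 * (0:4), y = 0)
#' link_tracks(det)                 # one track: steps of 2 px all link
#' @export
link_tracks <- function(detections, link_max_px = 10) {
  stopifnot(link_max_px > 0,
            all(c("frame", "x", "y") %in% names(detections)))
  det <- dplyr::arrange(tibble::as_tibble(detections), .data$frame)

  tracks_pts <- list()     # per track: list of c(frame, x, y)
  head_frame <- integer(0) # frame of each track's last point
  head_x <- double(0)
  head_y <- double(0)

  frames <- unique(det$frame)
  for (f in frames) {
    cur <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(cur)
    active <- which(head_frame == f - 1L)
    assigned_det <- rep(FALSE, nd)

    if (length(active) > 0 && nd > 0) {
      # all candidate pairs, nearest first; ties by track id then det index
      pairs <- expand.grid(ti = active, di = seq_len(nd))
      d <- sqrt((head_x[pairs$ti] - cur$x[pairs$di])^2 +
                  (head_y[pairs$ti] - cur$y[pairs$di])^2)
      ord <- order(d, pairs$ti, pairs$di)
      used_track <- rep(FALSE, length(head_frame))
      for (k in ord) {
        if (d[k] >= link_max_px) break
        ti <- pairs$ti[k]; di <- pairs$di[k]
        if (used_track[ti] || assigned_det[di]) next
        used_track[ti] <- TRUE
        assigned_det[di] <- TRUE
        tracks_pts[[ti]][[length(tracks_pts[[ti]]) + 1L]] <-
          c(f, cur$x[di], cur$y[di])
        head_frame[ti] <- f
        head_x[ti] <- cur$x[di]
        head_y[ti] <- cur$y[di]
      }
    }
    # unmatched detections seed new tracks
    for (di in which(!assigned_det)) {
      ti <- length(tracks_pts) + 1L
      tracks_pts[[ti]] <- list(c(f, cur$x[di], cur$y[di]))
      head_frame[ti] <- f
      head_x[ti] <- cur$x[di]
      head_y[ti] <- cur$y[di]
    }
  }

  if (length(tracks_pts) == 0L) {
    out <- tibble::tibble(track_id = integer(), frame = integer(),
                          x = double(), y = double())
  } else {
    out <- purrr::map_dfr(seq_along(tracks_pts), function(ti) {
      m <- do.call(rbind, tracks_pts[[ti]])
      tibble::tibble(track_id = ti, frame = as.integer(m[, 1]),
                     x = m[, 2], y = m[, 3])
    })
  }
  new_larva_tracks(out,
                   fps = attr(detections, "fps") %||% 3.75,
                   mm_per_px = attr(detections, "mm_per_px") %||% 0.3,
                   config = attr(detections, "config"))
}

#' Track durations in seconds
#'
#' Duration of a track with `n` points is `(n - 1) / fps`: the elapsed time
#' between its first and last frame. A single-point track has duration 0.
#'
#' @param tracks A `larva_tracks` tibble.
#' @param fps Frames per second; defaults to the table's metadata.
#' @return A tibble with `track_id`, `n_points`, `duration_s`.
#' @export
track_durations <- function(tracks, fps = attr(tracks, "fps") %||% 3.75) {
  stopifnot(fps > 0)
  tracks |>
    tibble::as_tibble() |>
    dplyr::count(.data$track_id, name = "n_points") |>
    dplyr::mutate(duration_s = (.data$n_points - 1) / fps)
}
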