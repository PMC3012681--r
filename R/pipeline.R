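#' Fraction of ground-truth frames covered by tracking
#'
#' For every ground-truth (blob, frame) position, checks whether any track
#' point in that frame lies within `tol_px` of the true center; the
#' completeness is the covered fraction. This is the success criterion for
#' tracking near arena edges: a method that loses the animal at the dish
#' edge covers fewer ground-truth frames.
#'
#' @param tracks A `larva_tracks` (or detections) tibble with `frame`, `x`,
#'   `y`.
#' @param truth Ground-truth tibble from [render_scene()].
#' @param tol_px Match radius in pixels; default 5.
#' @return A tibble with `blob_id`, `n_frames`, `n_covered`, `completeness`.
#' @export
track_completeness <- function(tracks, truth, tol_px = 5) {
  stopifnot(all(c("frame", "x", "y") %in% names(tracks)))
  tr <- tibble::as_tibble(tracks)[, c("frame", "x", "y")]
  tt <- tibble::as_tibble(truth)
  tt$covered <- vapply(seq_len(nrow(tt)), function(i) {
    cand <- tr[tr$frame == tt$frame[i], , drop = FALSE]
    nrow(cand) > 0 &&
      any((cand$x - tt$x[i])^2 + (cand$y - tt$y[i])^2 <= tol_px^2)
  }, logical(1))
  tt |>
    dplyr::group_by(.data$blob_id) |>
    dplyr::summarise(n_frames = dplyr::n(),
                     n_covered = sum(.data$covered),
                     completeness = mean(.data$covered),
                     .groups = "drop")
}

# resolve a movie argument: path or larva_movie
.as_movie <- function(movie, config) {
  if (inherits(movie, "larva_movie")) return(movie)
  if (!is.character(movie) || !file.exists(movie))
    stop("cannot read movie: no such file or directory: ", movie)
  load_movie(movie, fps = config$fps, mm_per_px = config$mm_per_px)
}

#' Run the tracking pipeline end to end
#'
#' Detects blobs in every frame, links them into tracks, smooths the
#' tracks, extracts instantaneous speeds, and (optionally) writes the
#' tracks, smoothed tracks, speed table, resolved configuration and a run
#' report to `out_dir`. The report makes a run reproducible: it records the
#' configuration used, per-frame detection counts, and track statistics.
#'
#' @param movie A [larva_movie] or a path readable by [load_movie()].
#' @param config A [pipeline_config].
#' @param method `"fast"` or `"baseline"`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `larva_report`: `config`, `method`, `n_frames`,
#'   `detections_per_frame` (tibble), `n_tracks`, `duration_mean_s`,
#'   `duration_sd_s`, `tracks`, `smoothed`, `speeds`, `paths` (files
#'   written).
#' @export
run_track <- function(movie, config = pipeline_config(),
                      method = c("fast", "baseline"), out_dir = NULL) {
  method <- match.arg(method)
  movie <- .as_movie(movie, config)
  det <- detect_blobs(movie, config, method)
  tracks <- link_tracks(det, config$link_max_px)
  smoothed <- smooth_tracks(tracks, config$smoothing_sigma_frames)
  speeds <- instantaneous_speed(smoothed, fps = movie$fps,
                                mm_per_px = movie$mm_per_px)
  counts <- tibble::tibble(frame = 0:(n_frames(movie) - 1L)) |>
    dplyr::left_join(dplyr::count(tibble::as_tibble(det), .data$frame),
                     by = "frame") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  dur <- track_durations(tracks, movie$fps)

  paths <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(
      tracks = file.path(out_dir, "tracks.csv"),
      smoothed = file.path(out_dir, "tracks_smoothed.csv"),
      speeds = file.path(out_dir, "speeds.csv"),
      config = file.path(out_dir, "config_used.yaml"),
      report = file.path(out_dir, "report.yaml")
    )
    write_tracks(tracks, paths[["tracks"]],
                 fps = movie$fps, mm_per_px = movie$mm_per_px)
    write_tracks(smoothed, paths[["smoothed"]],
                 fps = movie$fps, mm_per_px = movie$mm_per_px)
    write.csv(speeds, paths[["speeds"]], row.names = FALSE)
    write_config(config, paths[["config"]])
  }
  report <- structure(list(
    config = config, method = method, n_frames = n_frames(movie),
    detections_per_frame = counts, n_tracks = length(unique(tracks$track_id)),
    duration_mean_s = if (nrow(dur) > 0) mean(dur$duration_s) else NaN,
    duration_sd_s = if (nrow(dur) > 1) sd(dur$duration_s) else NaN,
    tracks = tracks, smoothed = smoothed, speeds = speeds, paths = paths
  ), class = "larva_report")
  if (!is.null(out_dir)) {
    yaml::write_yaml(list(
      method = method, n_frames = report$n_frames, n_tracks = report$n_tracks,
      duration_mean_s = report$duration_mean_s,
      duration_sd_s = report$duration_sd_s,
      mean_detections_per_frame = mean(counts$n)
    ), paths[["report"]])
  }
  report
}

#' @export
print.larva_report <- function(x, ...) {
  cat(sprintf("<larva_report> method=%s  frames=%d  tracks=%d\n",
              x$method, x$n_frames, x$n_tracks))
  cat(sprintf("  mean detections/frame: %.2f\n",
              mean(x$detections_per_frame$n)))
  if (!is.nan(x$duration_mean_s))
    cat(sprintf("  track duration: %.2f +/- %.2f s\n",
                x$duration_mean_s,
                ifelse(is.nan(x$duration_sd_s), 0, x$duration_sd_s)))
  invisible(x)
}

#' Compare background-subtraction tracking with the plain-threshold baseline
#'
#' Runs both methods on the same movie and reports per-frame
#' above-threshold object counts for each; when ground truth is supplied,
#' also reports per-method track completeness.
#'
#' @inheritParams run_track
#' @param truth Optional ground-truth tibble from [render_scene()].
#' @param tol_px Completeness match radius in pixels; default 5.
#' @return A list of class `larva_comparison`: `fast` and `baseline` run
#'   reports, `counts` (per-frame object counts, long format), and
#'   `completeness` (tibble, or `NULL` without truth).
#' @export
run_compare <- function(movie, config = pipeline_config(), out_dir = NULL,
                        truth = NULL, tol_px = 5) {
  movie <- .as_movie(movie, config)
  fast <- run_track(movie, config, "fast",
                    if (is.null(out_dir)) NULL else file.path(out_dir, "fast"))
  base <- run_track(movie, config, "baseline",
                    if (is.null(out_dir)) NULL else file.path(out_dir, "baseline"))
  counts <- dplyr::bind_rows(
    dplyr::mutate(fast$detections_per_frame, method = "fast"),
    dplyr::mutate(base$detections_per_frame, method = "baseline")
  )
  completeness <- NULL
  if (!is.null(truth)) {
    completeness <- dplyr::bind_rows(
      dplyr::mutate(track_completeness(fast$tracks, truth, tol_px),
                    method = "fast"),
      dplyr::mutate(track_completeness(base$tracks, truth, tol_px),
                    method = "baseline")
    )
  }
  if (!is.null(out_dir)) {
    write.csv(counts, file.path(out_dir, "object_counts.csv"),
              row.names = FALSE)
    if (!is.null(completeness))
      write.csv(completeness, file.path(out_dir, "completeness.csv"),
                row.names = FALSE)
  }
  structure(list(fast = fast, baseline = base, counts = counts,
                 completeness = completeness),
            class = "larva_comparison")
}

#' @export
print.larva_comparison <- function(x, ...) {
  cat("<larva_comparison>\n")
  s <- x$counts |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_objects = mean(.data$n),
                     max_objects = max(.data$n), .groups = "drop")
  print(s)
  if (!is.null(x$completeness)) print(x$completeness)
  invisible(x)
}

#' Render a scene to disk
#'
#' Writes the rendered movie (TIFF stack or AVI), the ground-truth track
#' CSV, and the scene parameters used.
#'
#' @param scene A [synth_scene].
#' @param out_dir Output directory.
#' @param format `"tiff"` or `"avi"`.
#' @return Invisibly, a list with `movie`, `truth` and file paths.
#' @export
run_synth <- function(scene, out_dir, format = c("tiff", "avi")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rendered <- render_scene(scene)
  movie_path <- file.path(out_dir,
                          if (format == "tiff") "movie.tif" else "movie.avi")
  save_movie(rendered$movie, movie_path)
  truth_path <- file.path(out_dir, "ground_truth.csv")
  tr <- tibble::tibble(track_id = rendered$truth$blob_id,
                       frame = rendered$truth$frame,
                       x = rendered$truth$x, y = rendered$truth$y)
  write_tracks(tr, truth_path, fps = scene$fps, mm_per_px = scene$mm_per_px)
  scene_path <- file.path(out_dir, "scene.yaml")
  sc <- unclass(scene)
  sc$blobs <- lapply(sc$blobs, function(b) {
    b$path <- as.data.frame(b$path); b
  })
  yaml::write_yaml(sc, scene_path)
  invisible(list(movie = rendered$movie, truth = rendered$truth,
                 paths = c(movie = movie_path, truth = truth_path,
                           scene = scene_path)))
}

#' Summary statistics for a saved track table
#'
#' Reads a track CSV, reports per-track durations and pooled speed
#' statistics after smoothing.
#'
#' @param tracks_path Path to a track CSV written by [write_tracks()].
#' @param sigma_frames Smoothing sigma; default 1.
#' @param bin_width Speed histogram bin width in mm/s; default 0.1.
#' @param out_dir Optional output directory for the histogram CSV.
#' @return A list with `durations`, `speeds`, `distribution`,
#'   `mean_speed_mm_s`.
#' @export
run_stats <- function(tracks_path, sigma_frames = 1.0, bin_width = 0.1,
                      out_dir = NULL) {
  tracks <- read_tracks(tracks_path)
  smoothed <- smooth_tracks(tracks, sigma_frames)
  speeds <- instantaneous_speed(smoothed)
  dist <- speed_distribution(speeds, bin_width)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(tibble::as_tibble(dist),
              file.path(out_dir, "speed_histogram.csv"), row.names = FALSE)
    write.csv(track_durations(tracks),
              file.path(out_dir, "durations.csv"), row.names = FALSE)
  }
  list(durations = track_durations(tracks), speeds = speeds,
       distribution = dist, mean_speed_mm_s = attr(dist, "mean_speed"))
}
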