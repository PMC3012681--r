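#' Pipeline configuration
#'
#' Bundles every numeric constant of the tracking method. The defaults are
#' the reference settings of the method: a detection threshold of 0.028 on
#' the background-subtracted residual (low enough to catch a translucent
#' larva once static objects are removed), cluster size bounds of 2 and
#' 100 pixels (inclusive), a maximum linking jump of 10 pixels between
#' consecutive frames (strictly less than; about 3 mm at the default scale),
#' 8-connectivity for component labeling, and a Gaussian track-smoothing
#' width of one frame interval.
#'
#' @param fast_threshold Threshold applied to the mean-minus-frame residual,
#'   in intensity units on `(0, 1)`. Default 0.028.
#' @param baseline_threshold Threshold applied to `1 - intensity` by the
#'   plain binary-threshold baseline (no background subtraction). Default
#'   0.09, a "high" setting that only picks up very dark pixels.
#' @param min_cluster_px,max_cluster_px Inclusive pixel-count bounds for
#'   cluster pruning. Defaults 2 and 100.
#' @param link_max_px Maximum centroid displacement joined into one track;
#'   distances `>= link_max_px` split tracks. Default 10.
#' @param connectivity Pixel adjacency for labeling, 4 or 8. Default 8.
#' @param smoothing_sigma_frames Gaussian smoothing sigma in frames.
#'   Default 1.
#' @param flicker_normalize Rescale each frame to the mean of frame means
#'   before subtraction, to cancel global illumination flicker. Default
#'   `FALSE`.
#' @param fps,mm_per_px Acquisition metadata defaults used when a movie does
#'   not carry its own.
#'
#' @return A list with class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$fast_threshold
#' @export
pipeline_config <- function(fast_threshold = 0.028,
                            baseline_threshold = 0.09,
                            min_cluster_px = 2L,
                            max_cluster_px = 100L,
                            link_max_px = 10,
                            connectivity = 8L,
                            smoothing_sigma_frames = 1.0,
                            flicker_normalize = FALSE,
                            fps = 3.75,
                            mm_per_px = 0.3) {
  stopifnot(
    fast_threshold > 0, fast_threshold < 1,
    baseline_threshold > 0, baseline_threshold < 1,
    min_cluster_px >= 1, min_cluster_px <= max_cluster_px,
    link_max_px > 0,
    connectivity %in% c(4L, 8L),
    smoothing_sigma_frames >= 0,
    is.logical(flicker_normalize),
    fps > 0, mm_per_px > 0
  )
  structure(
    list(
      fast_threshold = fast_threshold,
      baseline_threshold = baseline_threshold,
      min_cluster_px = as.integer(min_cluster_px),
      max_cluster_px = as.integer(max_cluster_px),
      link_max_px = link_max_px,
      connectivity = as.integer(connectivity),
      smoothing_sigma_frames = smoothing_sigma_frames,
      flicker_normalize = flicker_normalize,
      fps = fps,
      mm_per_px = mm_per_px
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read or write a pipeline configuration file
#'
#' Configurations are stored as YAML `key: value` text; unknown keys are an
#' error, missing keys take the package defaults.
#'
#' @param path File path.
#' @return `read_config()` returns a [pipeline_config]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A [pipeline_config].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
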