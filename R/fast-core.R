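#' Mean frame of a movie
#'
#' Pixelwise arithmetic mean over all frames, including frames that contain
#' the moving animal. The animal therefore leaves a faint ghost in the mean
#' of depth roughly (blob contrast) x (frames-on-pixel / n frames); the
#' detection threshold must exceed that ghost, which the default 0.028
#' comfortably does for movies longer than a few tens of frames.
#'
#' @param movie A [larva_movie] with at least one frame.
#' @return A numeric matrix in `[0, 1]`.
#' @export
average_frame <- function(movie) {
  stopifnot(inherits(movie, "larva_movie"))
  n <- n_frames(movie)
  if (n == 0L) stop("empty movie")
  rowMeans(movie$frames, dims = 2L)
}

#' Background-subtracted residual of one frame
#'
#' Computes `pmax(mean - frame, 0)`: static scene content cancels and only
#' pixels darker than their time average survive. Negatives are clipped
#' because the tracked animals are dark objects; brighter-than-average
#' pixels carry no signal for a one-sided threshold.
#'
#' @param mean_frame Matrix from [average_frame()].
#' @param frame A single frame matrix of the same shape.
#' @return Residual matrix with values in `[0, 1]`.
#' @export
subtract_frame <- function(mean_frame, frame) {
  if (!identical(dim(mean_frame), dim(frame)))
    stop("dimension error: mean and frame shapes differ")
  pmax(mean_frame - frame, 0)
}

#' Binarize a residual image
#'
#' Strictly greater-than comparison: `residual > t`. Strictness makes the
#' degenerate all-equal image yield an empty mask.
#'
#' @param residual Numeric matrix.
#' @param t Threshold in `(0, 1)`.
#' @return A logical matrix of the same shape.
#' @export
threshold_mask <- function(residual, t) {
  stopifnot(t > 0, t < 1)
  residual > t
}

#' Plain binary-threshold baseline mask
#'
#' The no-subtraction baseline: selects dark pixels directly by thresholding
#' `1 - intensity`, so a high threshold (e.g. 0.09) keeps only very dark
#' pixels. Static dark objects such as dish edges pass this mask along with
#' the animal, which is the failure mode background subtraction removes.
#'
#' @param frame A frame matrix in `[0, 1]`.
#' @inheritParams threshold_mask
#' @return A logical matrix.
#' @export
baseline_mask <- function(frame, t) {
  stopifnot(t > 0, t < 1)
  (1 - frame) > t
}

#' Normalize global illumination flicker
#'
#' Rescales each frame by (mean of all frame means) / (its own mean), then
#' clips to `[0, 1]`. A purely multiplicative global gain — such as the slow
#' beat produced by mains-powered lighting sampled by a camera with a
#' slightly mismatched clock — is cancelled exactly, making all frame means
#' equal.
#'
#' @param movie A [larva_movie]; every frame must have nonzero mean.
#' @return A [larva_movie] with equalized frame means.
#' @export
flicker_normalize <- function(movie) {
  stopifnot(inherits(movie, "larva_movie"))
  n <- n_frames(movie)
  means <- apply(movie$frames, 3L, mean)
  if (any(means == 0))
    stop("degenerate frame: zero mean intensity in frame ",
         which(means == 0)[1] - 1L)
  target <- mean(means)
  frames <- movie$frames * rep(target / means, each = prod(dim(movie$frames)[1:2]))
  frames <- pmin(pmax(frames, 0), 1)
  larva_movie(frames, fps = movie$fps, mm_per_px = movie$mm_per_px,
              source = paste0(movie$source, " (flicker-normalized)"))
}

#' Label connected pixel clusters
#'
#' Partitions the true pixels of a binary mask into maximal connected
#' components under 4- or 8-neighbour adjacency and returns one row per
#' cluster with its pixel count and unweighted centroid. Coordinates are
#' 0-based with `x` = column, `y` = row.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with columns `label`, `n_px`, `x`, `y`, ordered by
#'   label (raster order of first pixel).
#' @export
label_clusters <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- .cc_label(mask, as.integer(connectivity))
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), n_px = integer(),
                          x = double(), y = double()))
  }
  l <- lab[idx]
  nr <- nrow(mask)
  y <- (idx - 1L) %% nr        # 0-based row
  x <- (idx - 1L) %/% nr       # 0-based column
  n_px <- tabulate(l)
  tibble::tibble(
    label = seq_along(n_px),
    n_px = n_px,
    x = as.vector(rowsum(as.double(x), l)) / n_px,
    y = as.vector(rowsum(as.double(y), l)) / n_px
  )
}

#' Prune clusters by size
#'
#' Keeps clusters whose pixel count lies within `[min_px, max_px]`,
#' inclusive at both ends. Removes single-pixel speckle noise below the
#' minimum and oversized artifacts (e.g. a dish edge merged into one giant
#' component) above the maximum.
#'
#' @param clusters Tibble from [label_clusters()] (or with an `n_px`
#'   column).
#' @param min_px,max_px Inclusive bounds; defaults 2 and 100.
#' @return The filtered tibble.
#' @export
prune_clusters <- function(clusters, min_px = 2L, max_px = 100L) {
  stopifnot(min_px <= max_px)
  dplyr::filter(clusters, .data$n_px >= min_px, .data$n_px <= max_px)
}

#' Detect blobs in every frame of a movie
#'
#' The full per-frame detection pipeline. With `method = "fast"`:
#' (optional flicker normalization) -> mean frame -> per-frame residual
#' `pmax(mean - frame, 0)` -> threshold at `fast_threshold` -> connected
#' component labeling -> size pruning. With `method = "baseline"`: threshold
#' `1 - intensity` at `baseline_threshold` per frame -> labeling -> pruning
#' (no background subtraction; static dark objects survive).
#'
#' @param movie A [larva_movie].
#' @param config A [pipeline_config].
#' @param method `"fast"` (background subtraction) or `"baseline"`.
#' @return A tibble of class `larva_detections` with columns `frame`
#'   (0-based), `label`, `n_px`, `x`, `y`; frames with no surviving cluster
#'   contribute no rows.
#' @examples
#' mv <- larva_movie(array(0.9, c(16, 16, 4)))
#' nrow(detect_blobs(mv, pipeline_config()))   # static scene: 0 detections
#' @export
detect_blobs <- function(movie, config = pipeline_config(),
                         method = c("fast", "baseline")) {
  method <- match.arg(method)
  stopifnot(inherits(movie, "larva_movie"), inherits(config, "pipeline_config"))
  if (method == "fast" && isTRUE(config$flicker_normalize))
    movie <- flicker_normalize(movie)
  n <- n_frames(movie)
  mean_frame <- if (method == "fast") average_frame(movie) else NULL
  per_frame <- lapply(seq_len(n) - 1L, function(i) {
    fr <- movie_frame(movie, i)
    mask <- if (method == "fast") {
      threshold_mask(subtract_frame(mean_frame, fr), config$fast_threshold)
    } else {
      baseline_mask(fr, config$baseline_threshold)
    }
    cl <- prune_clusters(label_clusters(mask, config$connectivity),
                         config$min_cluster_px, config$max_cluster_px)
    if (nrow(cl) > 0) cl$frame <- i
    cl
  })
  out <- dplyr::bind_rows(per_frame)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(frame = integer(), label = integer(),
                          n_px = integer(), x = double(), y = double())
  } else {
    out <- dplyr::select(out, "frame", "label", "n_px", "x", "y")
  }
  structure(out,
            class = c("larva_detections", class(tibble::tibble())),
            config = config, method = method,
            n_frames = n, dims = dim(movie$frames)[1:2],
            fps = movie$fps, mm_per_px = movie$mm_per_px)
}
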