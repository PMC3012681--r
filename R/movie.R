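#' Grayscale movie container
#'
#' A `larva_movie` holds an ordered stack of grayscale frames as a 3-D numeric
#' array (`height x width x n_frames`) with all intensities in `[0, 1]`
#' (0 = black, 1 = white; larvae are dark objects on a light background),
#' together with the acquisition metadata needed to convert pixel
#' displacements into physical speeds.
#'
#' Coordinate convention used throughout the package: `x` is the column and
#' `y` the row, both 0-based, with pixel centers at integer coordinates.
#' Frame indices are 0-based in all tabular outputs.
#'
#' @param frames A 3-D numeric array (`h x w x n`), a list of equally sized
#'   numeric matrices, or a single matrix (treated as one frame).
#' @param fps Frames per second; default 3.75.
#' @param mm_per_px Spatial scale in millimetres per pixel; default 0.3.
#' @param source Provenance string recorded on the object.
#'
#' @return An object of class `larva_movie`.
#' @examples
#' mv <- larva_movie(array(0.5, c(8, 8, 3)))
#' n_frames(mv)
#' @export
larva_movie <- function(frames, fps = 3.75, mm_per_px = 0.3,
                        source = "in-memory") {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("empty movie: no frames supplied")
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("dimension error: frames differ in size")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[1, 1], dims[2, 1], length(frames)))
  } else if (is.matrix(frames)) {
    frames <- array(frames, c(dim(frames), 1L))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a matrix, list of matrices, or 3-D array")
  if (dim(frames)[3] == 0L) stop("empty movie: no frames supplied")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) stop("mm_per_px must be > 0")
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(
    list(frames = frames, fps = fps, mm_per_px = mm_per_px, source = source),
    class = "larva_movie"
  )
}

#' @rdname larva_movie
#' @param movie A `larva_movie`.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame from a movie
#'
#' @param movie A `larva_movie`.
#' @param i Frame index, 0-based to match the frame indices in detection and
#'   track tables.
#' @return A numeric matrix in `[0, 1]`.
#' @export
movie_frame <- function(movie, i) {
  stopifnot(i >= 0, i < n_frames(movie))
  movie$frames[, , i + 1L]
}

#' @export
print.larva_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<larva_movie> %d frame(s), %d x %d px, %.4g fps, %.4g mm/px [%s]\n",
    d[3], d[2], d[1], x$fps, x$mm_per_px, x$source
  ))
  invisible(x)
}

#' @export
dim.larva_movie <- function(x) dim(x$frames)

# collapse an h x w x channels array to grayscale by channel averaging
.to_gray <- function(px) {
  if (length(dim(px)) == 3L) {
    # drop a possible alpha channel before averaging
    nch <- min(dim(px)[3], 3L)
    px <- apply(px[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  px
}

#' Load a movie from disk
#'
#' Reads an uncompressed 8-bit grayscale AVI, a multi-page TIFF, or a
#' directory of lexicographically ordered PNG/TIFF frames. Intensities are
#' rescaled from the native bit depth to `[0, 1]`; colour frames are
#' converted to grayscale by channel averaging. The rescaling is affine and
#' order-preserving, so pixel ranks are unchanged by loading.
#'
#' @param path File (`.avi`, `.tif`, `.tiff`) or directory of frames.
#' @inheritParams larva_movie
#' @return A [larva_movie].
#' @seealso [save_movie()]
#' @export
load_movie <- function(path, fps = 3.75, mm_per_px = 0.3) {
  if (!file.exists(path))
    stop("cannot read movie: no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0L)
      stop("empty movie source: no PNG/TIFF frames in ", path)
    frames <- lapply(files, .read_frame_file)
  } else {
    ext <- tolower(tools::file_ext(path))
    frames <- switch(ext,
      avi = read_avi(path),
      tif = ,
      tiff = tiff::readTIFF(path, all = TRUE),
      stop("format error: unsupported movie format '.", ext, "'")
    )
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) == 0L) stop("empty movie source: ", path)
  }
  frames <- lapply(frames, .to_gray)
  larva_movie(frames, fps = fps, mm_per_px = mm_per_px, source = path)
}

.read_frame_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  px <- switch(ext,
    png = png::readPNG(f),
    tif = ,
    tiff = tiff::readTIFF(f),
    stop("format error: unsupported frame format '.", ext, "'")
  )
  if (is.list(px)) px <- px[[1]]
  px
}

#' Save a movie to disk
#'
#' Writes 8-bit quantized frames: a multi-page TIFF (`.tif`/`.tiff`), an
#' uncompressed grayscale AVI (`.avi`), or a numbered PNG sequence when
#' `path` is a directory. Quantization is the only loss: a save/load round
#' trip has pixelwise max absolute error at most 1/255, and is the identity
#' for movies whose values already sit on the 8-bit grid.
#'
#' @param movie A [larva_movie].
#' @param path Output file or directory.
#' @return `path`, invisibly.
#' @export
save_movie <- function(movie, path) {
  stopifnot(inherits(movie, "larva_movie"))
  n <- n_frames(movie)
  frames <- lapply(seq_len(n) - 1L, function(i) movie_frame(movie, i))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  } else if (ext == "avi") {
    write_avi(frames, path, fps = movie$fps)
  } else if (ext == "") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(n)) {
      png::writePNG(frames[[i]],
                    file.path(path, sprintf("frame_%05d.png", i - 1L)))
    }
  } else {
    stop("format error: unsupported output format '.", ext, "'")
  }
  invisible(path)
}
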