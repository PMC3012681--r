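#' Write and read track tables
#'
#' Track tables are CSVs with columns
#' `track_id,frame_index,x_px,y_px[,x_mm,y_mm,time_s]` preceded by
#' `#`-prefixed metadata lines carrying `fps` and `mm_per_px`, so a table is
#' self-describing. `read_tracks(write_tracks(t))` reproduces `t` exactly
#' for the integer columns and to full printed precision for coordinates.
#'
#' @param tracks A tibble with at least `track_id`, `frame`, `x`, `y`
#'   (pixel coordinates, 0-based frames), as produced by [link_tracks()].
#' @param path Output CSV path.
#' @param fps,mm_per_px Metadata written to the header; defaults are taken
#'   from attributes of `tracks` when present.
#' @param physical Also write `x_mm`, `y_mm`, `time_s` columns derived from
#'   the metadata. Default `TRUE`.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns a tibble of class `larva_tracks` with `fps` and `mm_per_px`
#'   attributes.
#' @export
write_tracks <- function(tracks, path,
                         fps = attr(tracks, "fps") %||% 3.75,
                         mm_per_px = attr(tracks, "mm_per_px") %||% 0.3,
                         physical = TRUE) {
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  out <- tibble::tibble(
    track_id = as.integer(tracks$track_id),
    frame_index = as.integer(tracks$frame),
    x_px = tracks$x,
    y_px = tracks$y
  )
  if (physical) {
    out$x_mm <- out$x_px * mm_per_px
    out$y_mm <- out$y_px * mm_per_px
    out$time_s <- out$frame_index / fps
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%.17g", fps),
               sprintf("# mm_per_px=%.17g", mm_per_px)), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    as.numeric(sub(".*=\\s*", "", hit[1]))
  }
  fps <- get_meta("fps", 3.75)
  mm_per_px <- get_meta("mm_per_px", 0.3)
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  df <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  need <- c("track_id", "frame_index", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (col in need) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(df$track_id) | is.na(df$frame_index) |
                 is.na(df$x_px) | is.na(df$y_px))
  if (length(bad) > 0) {
    line_no <- length(meta_idx) + 1L + bad[1]
    stop("parse error in ", path, " at line ", line_no,
         ": non-numeric or missing value")
  }
  out <- tibble::tibble(
    track_id = as.integer(df$track_id),
    frame = as.integer(df$frame_index),
    x = df$x_px,
    y = df$y_px
  )
  new_larva_tracks(out, fps = fps, mm_per_px = mm_per_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_larva_tracks <- function(df, fps, mm_per_px, config = NULL) {
  df <- tibble::as_tibble(as.data.frame(df))
  structure(df,
            class = c("larva_tracks", "tbl_df", "tbl", "data.frame"),
            fps = fps, mm_per_px = mm_per_px, config = config)
}
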