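# Minimal uncompressed AVI container support (RIFF, 'DIB ' video stream).
#
# The recording rigs this package targets store raw uncompressed video, and
# no installed R package speaks AVI, so the package carries a small
# reader/writer for the uncompressed subset: 8-bit palettized grayscale
# (what write_avi emits) and 24-bit BGR frames. Anything compressed is
# rejected with a format error.

.u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

# Write 8-bit grayscale frames (list of [0,1] matrices) as uncompressed AVI.
write_avi <- function(frames, path, fps = 3.75) {
  h <- nrow(frames[[1]])
  w <- ncol(frames[[1]])
  n <- length(frames)
  stride <- ((w + 3L) %/% 4L) * 4L
  fb <- stride * h                       # bytes per frame (stride is 4-aligned)

  chunk <- function(id, payload) c(charToRaw(id), .u32le(length(payload)), payload)
  list_chunk <- function(type, payload) chunk("LIST", c(charToRaw(type), payload))

  avih <- c(
    .u32le(round(1e6 / fps)),            # microseconds per frame
    .u32le(fb * fps), .u32le(0L),
    .u32le(16L),                         # AVIF_HASINDEX
    .u32le(n), .u32le(0L), .u32le(1L), .u32le(fb),
    .u32le(w), .u32le(h), .u32le(rep(0L, 4))
  )
  strh <- c(
    charToRaw("vids"), charToRaw("DIB "),
    .u32le(0L), .u16le(c(0L, 0L)), .u32le(0L),
    .u32le(1000L), .u32le(round(fps * 1000)),   # scale / rate
    .u32le(0L), .u32le(n), .u32le(fb), .u32le(-1L), .u32le(0L),
    .u16le(c(0L, 0L, w, h))
  )
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))  # BGRX grayscale palette
  strf <- c(
    .u32le(40L), .u32le(w), .u32le(h), .u16le(1L), .u16le(8L),
    .u32le(0L),                          # BI_RGB, uncompressed
    .u32le(fb), .u32le(0L), .u32le(0L), .u32le(256L), .u32le(0L),
    pal
  )
  hdrl <- list_chunk("hdrl", c(chunk("avih", avih),
                               list_chunk("strl", c(chunk("strh", strh),
                                                    chunk("strf", strf)))))

  encode <- function(fr) {
    # 8-bit quantize; DIB rows run bottom-up
    q <- matrix(as.integer(round(fr * 255)), nrow(fr), ncol(fr))
    rows <- matrix(0L, stride, h)
    rows[seq_len(w), ] <- t(q[h:1, , drop = FALSE])
    chunk("00db", as.raw(rows))
  }
  movi_payload <- do.call(c, lapply(frames, encode))
  movi <- list_chunk("movi", movi_payload)

  offs <- 4L + (seq_len(n) - 1L) * (8L + fb)     # relative to 'movi' fourcc
  idx <- do.call(c, lapply(offs, function(o)
    c(charToRaw("00db"), .u32le(16L), .u32le(o), .u32le(fb))))
  idx1 <- chunk("idx1", idx)

  body <- c(charToRaw("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("RIFF"), .u32le(length(body)), body), con)
  invisible(path)
}

# Read an uncompressed AVI; returns a list of [0,1] grayscale matrices.
read_avi <- function(path) {
  dat <- readBin(path, "raw", file.size(path))
  u32 <- function(off) sum(as.double(dat[off + 1:4]) * c(1, 256, 65536, 16777216))
  u16 <- function(off) sum(as.double(dat[off + 1:2]) * c(1, 256))
  fcc <- function(off) rawToChar(dat[off + 1:4])
  if (length(dat) < 12 || fcc(0) != "RIFF" || fcc(8) != "AVI ")
    stop("format error: not an AVI file: ", path)

  strf <- NULL
  frame_chunks <- list()

  walk <- function(from, to) {
    pos <- from
    while (pos + 8 <= to) {
      id <- fcc(pos)
      size <- u32(pos + 4)
      if (id == "LIST") {
        walk(pos + 12, pos + 8 + size)
      } else if (id == "strf" && is.null(strf)) {
        strf <<- dat[(pos + 8 + 1):(pos + 8 + size)]
      } else if (grepl("^..d[bc]$", id) && size > 0) {
        frame_chunks[[length(frame_chunks) + 1L]] <<-
          dat[(pos + 8 + 1):(pos + 8 + size)]
      }
      pos <- pos + 8 + size + size %% 2
    }
  }
  walk(12, length(dat))

  if (is.null(strf) || length(frame_chunks) == 0L)
    stop("format error: no uncompressed video stream found in ", path)
  bu32 <- function(off) sum(as.double(strf[off + 1:4]) * c(1, 256, 65536, 16777216))
  w <- bu32(4); h <- bu32(8)
  bits <- sum(as.double(strf[15:16]) * c(1, 256))
  compression <- bu32(16)
  if (compression != 0)
    stop("format error: compressed AVI streams are not supported")

  if (bits == 8) {
    # grayscale lookup from the palette (BGRX)
    pal <- matrix(as.double(strf[41:(40 + 1024)]), 4)
    lut <- colMeans(pal[1:3, ]) / 255
    stride <- ((w + 3) %/% 4) * 4
    decode <- function(ck) {
      rows <- matrix(as.integer(ck[seq_len(stride * h)]), stride, h)
      px <- t(rows[seq_len(w), , drop = FALSE])[h:1, , drop = FALSE]
      matrix(lut[px + 1L], h, w)
    }
  } else if (bits == 24) {
    stride <- ((3 * w + 3) %/% 4) * 4
    decode <- function(ck) {
      rows <- matrix(as.double(ck[seq_len(stride * h)]), stride, h)
      bgr <- (rows[seq(1, 3 * w, 3), ] + rows[seq(2, 3 * w, 3), ] +
                rows[seq(3, 3 * w, 3), ]) / 3
      t(bgr)[h:1, , drop = FALSE] / 255
    }
  } else {
    stop("format error: unsupported AVI bit depth: ", bits)
  }
  lapply(frame_chunks, decode)
}
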