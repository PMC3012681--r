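# run code with a temporary RNG seed, restoring global state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a synthetic recording scene
#'
#' A parametric description of a ground-truthed synthetic movie emulating
#' the recording conditions this package targets: one or more dark moving
#' blobs (larvae) over a light background, optionally a static
#' high-contrast dish-edge ring, a slow multiplicative illumination beat
#' (mains-powered lighting sampled by a camera with a slightly detuned
#' clock), and additive pixel noise. The seed fully determines the rendered
#' movie.
#'
#' @param width,height Frame size in pixels; defaults 640 x 480.
#' @param n_frames Number of frames.
#' @param fps Frames per second; default 3.75.
#' @param background_level Background intensity in `[0, 1]`; default 0.85.
#' @param ring `NULL`, or `list(center = c(x, y), radius_px, thickness_px,
#'   level)`: a static dark ring drawn at intensity `level` (default 0.35),
#'   emulating a petri-dish edge.
#' @param blobs List of blobs, each `list(path, radius_px, contrast)`:
#'   `path` is a tibble with `frame`, `x`, `y` giving the true center per
#'   frame; `radius_px` defaults to 4 (disc area about 50 px, inside the
#'   default pruning window); `contrast` is the intensity depth below the
#'   local background (0.4 emulates a dye-fed larva, 0.05 an undyed one).
#' @param flicker `list(amplitude, source_hz, capture_hz, detune_hz)`;
#'   defaults 0.03, 60, 30, 0.1. The light output oscillates at twice the
#'   mains frequency; the camera clock is detuned by `detune_hz`, so the
#'   sampled gain beats slowly across frames.
#' @param noise_sd Additive Gaussian pixel noise sd; default 0.01.
#' @param mm_per_px Spatial scale; default 0.3.
#' @param seed Integer seed; default 1.
#' @return An object of class `synth_scene`.
#' @seealso [render_scene()], [random_walk_path()]
#' @export
synth_scene <- function(width = 640L, height = 480L, n_frames = 100L,
                        fps = 3.75, background_level = 0.85,
                        ring = NULL, blobs = list(),
                        flicker = list(amplitude = 0.03, source_hz = 60,
                                       capture_hz = 30, detune_hz = 0.1),
                        noise_sd = 0.01, mm_per_px = 0.3, seed = 1L) {
  stopifnot(width >= 1, height >= 1, n_frames >= 1, fps > 0,
            background_level >= 0, background_level <= 1, noise_sd >= 0)
  flick_def <- list(amplitude = 0.03, source_hz = 60, capture_hz = 30,
                    detune_hz = 0.1)
  flicker <- utils::modifyList(flick_def, as.list(flicker))
  if (!is.null(ring)) {
    ring_def <- list(center = c(width / 2, height / 2),
                     radius_px = min(width, height) * 0.4,
                     thickness_px = 3, level = 0.35)
    ring <- utils::modifyList(ring_def, as.list(ring))
    if (ring$radius_px <= 0 || ring$thickness_px <= 0)
      stop("parameter error: ring radius and thickness must be positive")
  }
  blobs <- lapply(blobs, function(b) {
    b <- utils::modifyList(list(radius_px = 4, contrast = 0.4), as.list(b))
    if (is.null(b$path)) stop("parameter error: blob needs a path")
    if (b$radius_px <= 0) stop("parameter error: blob radius must be positive")
    if (b$contrast < 0 || b$contrast > 1)
      stop("parameter error: blob contrast must lie in [0, 1]")
    b
  })
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames), fps = fps,
                 background_level = background_level, ring = ring,
                 blobs = blobs, flicker = flicker, noise_sd = noise_sd,
                 mm_per_px = mm_per_px, seed = as.integer(seed)),
            class = "synth_scene")
}

# logical mask of the ring pixels (0-based pixel-center coordinates)
.ring_mask <- function(width, height, ring) {
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), width), height, width)
  r <- sqrt((x - ring$center[1])^2 + (y - ring$center[2])^2)
  abs(r - ring$radius_px) <= ring$thickness_px / 2
}

.disc_mask <- function(width, height, cx, cy, radius) {
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), width), height, width)
  (x - cx)^2 + (y - cy)^2 <= radius^2
}

#' Render a synthetic scene to a movie plus ground truth
#'
#' Each frame is
#' `clamp(gain_t * (background - ring - sum(blob discs * contrast)) + noise)`.
#' The flicker gain is sampled at the true frame times:
#' `gain_k = 1 + amplitude * sin(2 * pi * (2 * source_hz + detune_hz) * k / fps)`.
#' At 3.75 fps the 120 Hz component aliases exactly to zero frequency and
#' the detuning survives as a slow beat across frames — the mechanism that
#' makes mains flicker visible in real recordings. Rendering is
#' deterministic given the scene seed.
#'
#' @param scene A [synth_scene].
#' @return A list with `movie` (a [larva_movie]) and `truth`, a tibble of
#'   class `larva_truth` with `blob_id`, `frame`, `x`, `y` (true centers);
#'   the static-pixel mask (ring) is attached as attribute
#'   `static_pixels`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "synth_scene"))
  w <- scene$width; h <- scene$height; n <- scene$n_frames

  static_img <- matrix(scene$background_level, h, w)
  ring_px <- matrix(FALSE, h, w)
  if (!is.null(scene$ring)) {
    ring_px <- .ring_mask(w, h, scene$ring)
    static_img[ring_px] <- scene$ring$level
  }

  paths <- lapply(scene$blobs, function(b) {
    p <- b$path
    stopifnot(all(c("frame", "x", "y") %in% names(p)), nrow(p) == n)
    dplyr::arrange(tibble::as_tibble(p), .data$frame)
  })

  fl <- scene$flicker
  k <- 0:(n - 1)
  gain <- 1 + fl$amplitude *
    sin(2 * pi * (2 * fl$source_hz + fl$detune_hz) * k / scene$fps)

  frames <- .with_seed(scene$seed, {
    lapply(seq_len(n), function(i) {
      img <- static_img
      for (bi in seq_along(scene$blobs)) {
        b <- scene$blobs[[bi]]
        p <- paths[[bi]]
        disc <- .disc_mask(w, h, p$x[i], p$y[i], b$radius_px)
        img[disc] <- img[disc] - b$contrast
      }
      img <- img * gain[i]
      if (scene$noise_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, scene$noise_sd), h, w)
      pmin(pmax(img, 0), 1)
    })
  })

  movie <- larva_movie(frames, fps = scene$fps, mm_per_px = scene$mm_per_px,
                       source = sprintf("synthetic (seed %d)", scene$seed))
  truth <- purrr::map_dfr(seq_along(paths), function(bi) {
    tibble::tibble(blob_id = bi, frame = paths[[bi]]$frame,
                   x = paths[[bi]]$x, y = paths[[bi]]$y)
  })
  if (length(paths) == 0L)
    truth <- tibble::tibble(blob_id = integer(), frame = integer(),
                            x = double(), y = double())
  truth <- structure(truth, class = c("larva_truth", class(tibble::tibble())),
                     static_pixels = ring_px,
                     fps = scene$fps, mm_per_px = scene$mm_per_px)
  list(movie = movie, truth = truth)
}

#' Correlated random-walk trajectory
#'
#' Constant step length `speed_mm_s / (fps * mm_per_px)` pixels per frame
#' with Gaussian heading increments of sd `turn_sd_rad`, emulating a
#' crawling larva; the walk reflects off the arena edges.
#'
#' @param n_frames Number of positions (frames 0-based `0:(n_frames - 1)`).
#' @param speed_mm_s Ground-truth speed in mm/s; default 0.76.
#' @param fps,mm_per_px Acquisition scale; defaults 3.75 and 0.3.
#' @param turn_sd_rad Heading increment sd per frame in radians; default 0.2.
#' @param seed Integer seed.
#' @param start Starting position `c(x, y)`; defaults to the arena center.
#' @param heading0 Initial heading in radians; default 0.
#' @param arena `c(width, height)` of the reflecting arena; default
#'   640 x 480.
#' @return A tibble with `frame`, `x`, `y`.
#' @export
random_walk_path <- function(n_frames, speed_mm_s = 0.76, fps = 3.75,
                             mm_per_px = 0.3, turn_sd_rad = 0.2, seed = 1L,
                             start = NULL, heading0 = 0,
                             arena = c(640, 480)) {
  stopifnot(speed_mm_s >= 0, n_frames >= 1)
  step <- speed_mm_s / (fps * mm_per_px)
  if (is.null(start)) start <- c(arena[1] / 2, arena[2] / 2)
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- start[1]; y[1] <- start[2]
  turns <- if (n_frames > 1) {
    if (turn_sd_rad > 0)
      .with_seed(seed, stats::rnorm(n_frames - 1, 0, turn_sd_rad))
    else rep(0, n_frames - 1)
  } else numeric(0)
  heading <- heading0
  for (i in seq_len(n_frames - 1L)) {
    heading <- heading + turns[i]
    nx <- x[i] + step * cos(heading)
    ny <- y[i] + step * sin(heading)
    if (nx < 0 || nx > arena[1] - 1) {
      heading <- pi - heading
      nx <- min(max(nx, -nx), 2 * (arena[1] - 1) - nx)
    }
    if (ny < 0 || ny > arena[2] - 1) {
      heading <- -heading
      ny <- min(max(ny, -ny), 2 * (arena[2] - 1) - ny)
    }
    x[i + 1L] <- nx; y[i + 1L] <- ny
  }
  tibble::tibble(frame = 0:(n_frames - 1L), x = x, y = y)
}

#' Add centroid jitter to a trajectory
#'
#' Adds iid per-axis Gaussian noise to a path, emulating centroid
#' localization error, and returns it as a single track — useful for
#' feeding the kinematics stage without rendering a movie.
#'
#' @param path Tibble with `frame`, `x`, `y`.
#' @param jitter_sd_px Per-axis noise sd in pixels.
#' @param seed Integer seed.
#' @param track_id Track id for the output; default 1.
#' @param fps,mm_per_px Metadata attached to the output.
#' @return A `larva_tracks` tibble.
#' @export
jittered_track <- function(path, jitter_sd_px, seed = 1L, track_id = 1L,
                           fps = 3.75, mm_per_px = 0.3) {
  stopifnot(jitter_sd_px >= 0)
  n <- nrow(path)
  noise <- if (jitter_sd_px > 0)
    .with_seed(seed, matrix(stats::rnorm(2 * n, 0, jitter_sd_px), n, 2))
  else matrix(0, n, 2)
  new_larva_tracks(
    tibble::tibble(track_id = as.integer(track_id), frame = path$frame,
                   x = path$x + noise[, 1], y = path$y + noise[, 2]),
    fps = fps, mm_per_px = mm_per_px
  )
}

#' Preset scenes reproducing the benchmark scenarios
#'
#' `scene_edge_crossing()` builds the dish-edge scenario: a blob crossing a
#' static dark ring on a straight constant-velocity path. The ring is a
#' 16 px wide band — at typical magnification a dish wall viewed obliquely
#' is a dark band wider than a larva, so a blob can be fully engulfed by
#' it. In the dyed
#' variant (contrast 0.4, ring at 0.35) background subtraction keeps the
#' blob visible on the ring because the blob is darker than the ring's time
#' average; in the undyed variant the higher exposure needed to resolve a
#' translucent larva makes the ring nearly black (level 0.02) while the
#' blob is faint (contrast 0.05), so a blob on the ring saturates into it
#' and is subtracted along with it — the edge-merging failure. The
#' background is set to 0.95 (bright-field, mildly overexposed) so the
#' plain-threshold baseline at 0.09 separates background from dark pixels.
#' Flicker is off in edge scenes so the edge effect is isolated;
#' `scene_flicker()` conversely has no ring. `scene_plain_blob()` is a
#' single dyed blob over a clean background.
#'
#' @param dyed Dyed (`TRUE`, contrast 0.4) or undyed (`FALSE`, 0.05) blob.
#' @param width,height Frame size; small defaults keep rendering fast.
#' @param n_frames Frames; default 40.
#' @param seed Scene seed.
#' @return A [synth_scene].
#' @export
scene_edge_crossing <- function(dyed = TRUE, width = 160L, height = 120L,
                                n_frames = 40L, seed = 1L) {
  path <- tibble::tibble(frame = 0:(n_frames - 1L),
                         x = 60 + 2 * (0:(n_frames - 1L)),
                         y = height / 2)
  synth_scene(
    width = width, height = height, n_frames = n_frames,
    background_level = 0.95,
    ring = list(center = c(width / 2, height / 2), radius_px = 45,
                thickness_px = 16, level = if (dyed) 0.35 else 0.02),
    blobs = list(list(path = path, radius_px = 4,
                      contrast = if (dyed) 0.4 else 0.05)),
    flicker = list(amplitude = 0),
    noise_sd = 0.01, seed = seed
  )
}

#' @rdname scene_edge_crossing
#' @param amplitude Flicker gain amplitude; default 0.03.
#' @export
scene_flicker <- function(width = 160L, height = 120L, n_frames = 75L,
                          amplitude = 0.03, seed = 1L) {
  path <- random_walk_path(n_frames, seed = seed + 1L,
                           arena = c(width, height),
                           start = c(width / 2, height / 2))
  synth_scene(width = width, height = height, n_frames = n_frames,
              background_level = 0.85,
              blobs = list(list(path = path, radius_px = 4, contrast = 0.4)),
              flicker = list(amplitude = amplitude),
              noise_sd = 0.01, seed = seed)
}

#' @rdname scene_edge_crossing
#' @param contrast Blob contrast depth; default 0.4 (dyed).
#' @export
scene_plain_blob <- function(width = 160L, height = 120L, n_frames = 60L,
                             contrast = 0.4, seed = 1L) {
  path <- random_walk_path(n_frames, seed = seed + 1L,
                           arena = c(width, height),
                           start = c(width / 2, height / 2))
  synth_scene(width = width, height = height, n_frames = n_frames,
              background_level = 0.85,
              blobs = list(list(path = path, radius_px = 4,
                                contrast = contrast)),
              flicker = list(amplitude = 0),
              noise_sd = 0.01, seed = seed)
}
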