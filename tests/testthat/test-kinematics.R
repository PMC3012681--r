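test_that("sigma zero smoothing is the identity", {
  tr <- jittered_track(tibble::tibble(frame = 0:30, x = runif(31, 0, 50),
                                      y = runif(31, 0, 50)), 0)
  sm <- smooth_tracks(tr, 0)
  expect_equal(sm$x, tr$x)
  expect_equal(sm$y, tr$y)
  expect_equal(sm$frame, tr$frame)
})

test_that("straight constant-velocity tracks are invariant in the interior", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:40,
                       x = 5 + 0.7 * (0:40), y = 3 + 0.2 * (0:40))
  sm <- smooth_tracks(tr, 1.0)
  interior <- 6:36  # beyond the 4-sigma kernel reach of either end
  expect_equal(sm$x[interior], tr$x[interior], tolerance = 1e-9)
  expect_equal(sm$y[interior], tr$y[interior], tolerance = 1e-9)
  # length and frame indices always preserved
  expect_equal(nrow(sm), nrow(tr))
  expect_equal(range(sm$frame), range(tr$frame))
})

test_that("smoothing matches the direct weighted-sum oracle", {
  set.seed(61)
  for (sigma in c(0.5, 1.0, 2.3)) {
    path <- tibble::tibble(frame = 0:49, x = 10 + 0.5 * (0:49), y = 20)
    tr <- jittered_track(path, 0.25, seed = 62)
    sm <- smooth_tracks(tr, sigma)
    expect_equal(sm$x, oracle_smooth(tr$x, sigma), tolerance = 1e-9)
    expect_equal(sm$y, oracle_smooth(tr$y, sigma), tolerance = 1e-9)
  }
})

test_that("smoothing reduces jitter variance about the true line", {
  set.seed(63)
  path <- tibble::tibble(frame = 0:199, x = 10 + 0.5 * (0:199), y = 40)
  tr <- jittered_track(path, 0.3, seed = 64)
  sm <- smooth_tracks(tr, 1.0)
  v_raw <- var(tr$y - path$y)
  v_sm <- var(sm$y - path$y)
  expect_lt(v_sm, v_raw)
})

test_that("smoothing displacements are Euclidean distances in micrometres", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:4, x = c(0, 1, 2, 3, 4), y = 0)
  expect_true(all(smoothing_displacements(tr, tr, 0.3)$displacement_um == 0))

  sm <- tr; sm$x[3] <- sm$x[3] + 1
  d <- smoothing_displacements(tr, sm, 0.3)$displacement_um
  expect_equal(d[3], 300)
  expect_equal(sum(d > 0), 1)

  expect_error(smoothing_displacements(tr, sm[1:3, ], 0.3), "dimension")
})

test_that("most smoothing displacements of jittered tracks stay below 200 um", {
  disp <- unlist(lapply(1:30, function(i) {
    path <- tibble::tibble(frame = 0:99, x = 10 + 0.5 * (0:99), y = 50)
    tr <- jittered_track(path, 0.25, seed = 700 + i)
    sm <- smooth_tracks(tr, 1.0)
    smoothing_displacements(tr, sm, 0.3)$displacement_um
  }))
  expect_gt(mean(disp < 200), 0.9)
})

test_that("instantaneous speed converts px/frame steps to mm/s", {
  still <- tibble::tibble(track_id = 1L, frame = 0:9, x = 5, y = 5)
  sp <- instantaneous_speed(still, fps = 3.75, mm_per_px = 0.3)
  expect_equal(nrow(sp), 9)
  expect_true(all(sp$speed_mm_s == 0))

  walk <- tibble::tibble(track_id = 1L, frame = 0:9, x = 0:9, y = 0)
  sp2 <- instantaneous_speed(walk, fps = 3.75, mm_per_px = 0.3)
  expect_true(all(abs(sp2$speed_mm_s - 1.125) < 1e-12))

  short <- tibble::tibble(track_id = 1L, frame = 0L, x = 0, y = 0)
  expect_equal(nrow(instantaneous_speed(short)), 0)
})

test_that("speed of a rendered constant-velocity blob is recovered within 5%", {
  n <- 60
  step <- 0.76 / (3.75 * 0.3)
  path <- tibble::tibble(frame = 0:(n - 1), x = 20 + step * (0:(n - 1)), y = 60)
  sc <- synth_scene(width = 160, height = 120, n_frames = n,
                    background_level = 0.85,
                    blobs = list(list(path = path, radius_px = 4,
                                      contrast = 0.4)),
                    flicker = list(amplitude = 0), noise_sd = 0.01, seed = 3)
  rend <- render_scene(sc)
  rep <- run_track(rend$movie)
  # restrict to the long (real) track; speckle tracks are single-frame
  dur <- track_durations(rep$tracks)
  main_id <- dur$track_id[which.max(dur$n_points)]
  sp <- rep$speeds[rep$speeds$track_id == main_id, ]
  expect_lt(abs(mean(sp$speed_mm_s) - 0.76) / 0.76, 0.05)
})

test_that("speed estimates are unbiased across seeds for jittered tracks", {
  means <- vapply(1:50, function(i) {
    path <- tibble::tibble(frame = 0:99, x = 10 + 0.676 * (0:99), y = 50)
    tr <- jittered_track(path, 0.15, seed = 900 + i)
    sm <- smooth_tracks(tr, 1.0)
    mean(instantaneous_speed(sm, 3.75, 0.3)$speed_mm_s)
  }, numeric(1))
  truth <- 0.676 * 0.3 * 3.75
  expect_lt(abs(mean(means) - truth) / truth, 0.02)
})

test_that("speed distributions pool and normalize correctly", {
  const <- tibble::tibble(track_id = 1L, frame = 0:10, x = (0:10) * 0.5, y = 0)
  sp <- instantaneous_speed(const, 3.75, 0.3)
  d <- speed_distribution(sp, bin_width = 0.1)
  expect_equal(sum(d$count > 0), 1)
  expect_equal(sum(d$density) * 0.1, 1)

  # two equal-length cohorts at speeds a and b split the mass 50/50
  a <- tibble::tibble(track_id = 1L, frame = 0:10, x = (0:10) * 0.2, y = 0)
  b <- tibble::tibble(track_id = 2L, frame = 0:10, x = (0:10) * 1.0, y = 0)
  d2 <- speed_distribution(list(instantaneous_speed(a, 3.75, 0.3),
                                instantaneous_speed(b, 3.75, 0.3)), 0.1)
  occupied <- d2[d2$count > 0, ]
  expect_equal(nrow(occupied), 2)
  expect_equal(occupied$count[1], occupied$count[2])

  empty <- speed_distribution(list(), 0.1)
  expect_equal(nrow(empty), 0)
})

test_that("identically generated cohorts have near-identical mean speeds", {
  cohort <- function(seed0) {
    lapply(1:20, function(i) {
      path <- random_walk_path(80, speed_mm_s = 0.76, seed = seed0 + i,
                               arena = c(300, 300))
      tr <- jittered_track(path, 0.2, seed = seed0 + 500 + i)
      instantaneous_speed(smooth_tracks(tr, 1.0), 3.75, 0.3)
    })
  }
  m1 <- attr(speed_distribution(cohort(1000)), "mean_speed")
  m2 <- attr(speed_distribution(cohort(2000)), "mean_speed")
  expect_lt(abs(m1 - m2), 0.05)
})
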