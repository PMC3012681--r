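test_that("average_frame is the pixelwise arithmetic mean", {
  f <- matrix(runif(16), 4, 4)
  mv <- larva_movie(list(f, f, f))
  expect_equal(average_frame(mv), f)

  mv2 <- larva_movie(list(matrix(0.2, 4, 4), matrix(0.6, 4, 4)))
  expect_true(all(average_frame(mv2) == 0.4))

  # 50 random frames against an independently accumulated per-pixel sum
  set.seed(21)
  frames <- replicate(50, matrix(runif(64), 8, 8), simplify = FALSE)
  acc <- matrix(0, 8, 8)
  for (fr in frames) acc <- acc + fr
  expect_equal(average_frame(larva_movie(frames)), acc / 50,
               tolerance = 1e-9)
})

test_that("subtract_frame keeps only darker-than-average pixels", {
  m <- matrix(0.5, 6, 6)
  expect_true(all(subtract_frame(m, m) == 0))

  f <- m; f[3, 4] <- 0.2
  res <- subtract_frame(m, f)
  expect_equal(res[3, 4], 0.3)
  expect_equal(sum(res > 0), 1)

  # brighter-than-average pixels clip to zero
  f2 <- m; f2[2, 2] <- 0.9
  expect_true(all(subtract_frame(m, f2) == 0))

  expect_error(subtract_frame(m, matrix(0.5, 6, 7)), "dimension")
})

test_that("residual of a moving dark patch is supported on the patch", {
  base <- matrix(0.8, 20, 20)
  f_patch <- base
  f_patch[10:12, 5:7] <- 0.3
  frames <- c(replicate(19, base, simplify = FALSE), list(f_patch))
  mv <- larva_movie(frames)
  res <- subtract_frame(average_frame(mv), f_patch)
  inside <- matrix(FALSE, 20, 20); inside[10:12, 5:7] <- TRUE
  # strong residual inside the patch, only mean-leakage elsewhere
  expect_true(all(res[inside] > 0.4))
  expect_true(all(res[!inside] < 1e-9))
})

test_that("thresholding is strict and monotone in the threshold", {
  z <- matrix(0, 8, 8)
  expect_equal(sum(threshold_mask(z, 0.028)), 0)

  r <- z; r[4, 4] <- 0.3
  expect_equal(sum(threshold_mask(r, 0.028)), 1)
  expect_equal(sum(threshold_mask(r, 0.3)), 0)  # strict: equal fails

  set.seed(9)
  res <- matrix(runif(400), 20, 20)
  ts <- seq(0.05, 0.95, by = 0.05)
  counts <- vapply(ts, function(t) sum(threshold_mask(res, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline mask selects dark pixels without background removal", {
  white <- matrix(1, 8, 8)
  expect_equal(sum(baseline_mask(white, 0.5)), 0)
  expect_equal(sum(baseline_mask(white, 0.01)), 0)

  f <- white; f[2, 3] <- 0
  m <- baseline_mask(f, 0.09)
  expect_true(m[2, 3])
  expect_equal(sum(m), 1)

  # dark ring + dark blob: any threshold catching the blob also marks ring
  sc <- scene_edge_crossing(dyed = FALSE, seed = 2)
  rend <- render_scene(sc)
  ring <- attr(rend$truth, "static_pixels")
  fr <- movie_frame(rend$movie, 5)
  for (t in c(0.073, 0.09, 0.15)) {
    m <- baseline_mask(fr, t)
    blob_seen <- any(m & !ring)
    if (blob_seen) expect_gt(sum(m & ring), 0)
  }
})

test_that("flicker normalization equalizes frame means", {
  set.seed(3)
  f <- matrix(runif(100, 0.3, 0.7), 10, 10)
  mv <- larva_movie(list(f, f, f))
  out <- flicker_normalize(mv)
  expect_equal(out$frames, mv$frames, tolerance = 1e-9)

  mv2 <- larva_movie(list(matrix(0.4, 5, 5), matrix(0.6, 5, 5)))
  out2 <- flicker_normalize(mv2)
  expect_true(all(abs(out2$frames - 0.5) < 1e-12))

  gains <- 1 + 0.05 * sin(2 * pi * (0:19) / 7)
  frames <- lapply(gains, function(g) f * g)
  out3 <- flicker_normalize(larva_movie(frames))
  means <- apply(out3$frames, 3, mean)
  expect_lt(max(means) - min(means), 1e-9)

  expect_error(flicker_normalize(larva_movie(list(matrix(0, 4, 4)))),
               "degenerate")
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(77)
  for (i in 1:100) {
    mask <- random_mask(32, 32, p = runif(1, 0.1, 0.6))
    for (conn in c(4L, 8L)) {
      got <- label_clusters(mask, conn)
      ref <- oracle_label(mask, conn)
      expect_equal(nrow(got), max(ref))
      # identical partitions of the true pixels
      lab_img <- larvatrack:::.cc_label(mask, conn)
      expect_identical(partition_of(lab_img), partition_of(ref))
      # per-cluster sizes agree with the oracle partition
      expect_identical(sort(got$n_px),
                       sort(as.integer(lengths(partition_of(ref)))))
    }
  }
})

test_that("labeling agrees with EBImage on 4-connectivity", {
  set.seed(13)
  for (i in 1:10) {
    mask <- random_mask(24, 24, 0.4)
    ours <- larvatrack:::.cc_label(mask, 4L)
    ref <- EBImage::bwlabel(mask * 1)
    expect_identical(partition_of(ours), partition_of(ref))
  }
})

test_that("connectivity handles diagonal adjacency as specified", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_clusters(m, 8L)), 1)
  expect_equal(nrow(label_clusters(m, 4L)), 2)
})

test_that("cluster centroids are unweighted means in 0-based x/y", {
  m <- matrix(FALSE, 10, 12)
  m[3:6, 5:9] <- TRUE  # rows 3..6 (y 2..5), cols 5..9 (x 4..8)
  cl <- label_clusters(m, 8L)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_px, 20L)
  expect_equal(cl$x, 6)    # (4+8)/2
  expect_equal(cl$y, 3.5)  # (2+5)/2
})

test_that("pruning keeps sizes within the inclusive bounds", {
  cl <- tibble::tibble(label = 1:4, n_px = c(1L, 2L, 100L, 101L),
                       x = 0, y = 0)
  kept <- prune_clusters(cl, 2L, 100L)
  expect_equal(sort(kept$n_px), c(2L, 100L))

  expect_equal(nrow(prune_clusters(cl[0, ], 2L, 100L)), 0)
  expect_equal(prune_clusters(cl, 1L, .Machine$integer.max), cl)
})

test_that("a static scene yields zero detections under subtraction", {
  set.seed(4)
  f <- matrix(runif(400, 0.2, 0.9), 20, 20)
  mv <- larva_movie(replicate(8, f, simplify = FALSE))
  for (t in c(1e-5, 0.028, 0.5)) {
    det <- detect_blobs(mv, pipeline_config(fast_threshold = t), "fast")
    expect_equal(nrow(det), 0)
  }
})

test_that("a dyed blob is detected in nearly every frame at 0.028", {
  rend <- render_scene(scene_plain_blob(contrast = 0.4, seed = 6))
  det <- detect_blobs(rend$movie, pipeline_config(), "fast")
  truth <- rend$truth
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    d <- det[det$frame == truth$frame[i], ]
    nrow(d) > 0 &&
      min(sqrt((d$x - truth$x[i])^2 + (d$y - truth$y[i])^2)) <= 2
  }, logical(1))
  # >= 1 detection within 2 px of ground truth in >= 95% of frames
  expect_gte(mean(hits), 0.95)
})

test_that("the baseline keeps static ring objects in every frame", {
  rend <- render_scene(scene_edge_crossing(dyed = TRUE, seed = 8))
  ring <- attr(rend$truth, "static_pixels")
  # retain large clusters so the dish edge is visible as an object
  cfg <- pipeline_config(baseline_threshold = 0.073,
                         max_cluster_px = 1000000L)
  det <- detect_blobs(rend$movie, cfg, "baseline")
  for (f in 0:(n_frames(rend$movie) - 1)) {
    d <- det[det$frame == f, ]
    big <- d[d$n_px > 500, ]
    expect_gt(nrow(big), 0)
  }
})
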