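# Independent oracles used across tests. These deliberately use naive
# algorithms (queue flood fill, direct weighted sums, exhaustive pair
# scans) so they share no code with the implementation they check.

# Connected-component labeling by breadth-first flood fill over a pixel
# queue; labels in column-major raster order of the first pixel.
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc] || lab[rr, cc] != 0L) next
      cur <- cur + 1L
      queue <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          r2 <- p[1] + o[1]; c2 <- p[2] + o[2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# canonical form of a labeling: list of sorted pixel-index sets, sorted by
# first pixel, so two labelings can be compared independent of label values
partition_of <- function(lab) {
  sets <- split(which(lab > 0), lab[lab > 0])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# direct per-point Gaussian weighted sum (truncated 4 sigma, renormalized)
oracle_smooth <- function(v, sigma) {
  n <- length(v)
  if (sigma <= 0) return(v)
  r <- max(1, ceiling(4 * sigma))
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; wsum <- 0
    for (k in -r:r) {
      j <- i + k
      if (j < 1 || j > n) next
      w <- exp(-k^2 / (2 * sigma^2))
      acc <- acc + w * v[j]
      wsum <- wsum + w
    }
    out[i] <- acc / wsum
  }
  out
}

# greedy nearest-pair matching by exhaustive scan: repeatedly find the
# global minimum-distance (head, detection) pair below the cutoff
oracle_match <- function(heads, dets, link_max) {
  pairs <- list()
  used_h <- rep(FALSE, nrow(heads))
  used_d <- rep(FALSE, nrow(dets))
  repeat {
    best <- NULL; best_d <- Inf
    for (i in seq_len(nrow(heads))) {
      if (used_h[i]) next
      for (j in seq_len(nrow(dets))) {
        if (used_d[j]) next
        d <- sqrt((heads$x[i] - dets$x[j])^2 + (heads$y[i] - dets$y[j])^2)
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
             (i < best[1] || (i == best[1] && j < best[2])))) {
          best <- c(i, j); best_d <- d
        }
      }
    }
    if (is.null(best) || best_d >= link_max) break
    used_h[best[1]] <- TRUE
    used_d[best[2]] <- TRUE
    pairs[[length(pairs) + 1]] <- best
  }
  pairs
}

# random small binary mask generator
random_mask <- function(nr, nc, p = 0.3) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
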