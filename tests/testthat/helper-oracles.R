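# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Flood-fill connected-component count/labels (6-connectivity), queue-based,
# plain R: independent of the C++ labeling kernel.
r_flood_label6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (q - 1L) %/% (d[1] * d[2])
      r <- (q - 1L) %% (d[1] * d[2])
      j <- r %/% d[1]; i <- r %% d[1]
      for (step in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                        c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
        ii <- i + step[1]; jj <- j + step[2]; kk <- k + step[3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] || kk < 0 || kk >= d[3])
          next
        qq <- 1L + ii + d[1] * (jj + d[2] * kk)
        if (mask[qq] && lab[qq] == 0L) {
          lab[qq] <- nxt
          queue <- c(queue, qq)
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu: for every internal bin edge, split the actual values and
# evaluate the between-class variance directly; return the lowest maximizing
# edge.
r_otsu_brute <- function(x, n_bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best <- -Inf; best_edge <- NA_real_
  for (k in 2:n_bins) {
    t <- edges[k]
    lo <- x[x < t]; hi <- x[x >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-300 && sb != best) { best <- sb; best_edge <- t }
  }
  best_edge
}

# Exposed voxel faces of a binary mask (count of foreground faces adjacent to
# background or the volume border), in face units.
r_face_count <- function(mask) {
  d <- dim(mask)
  m <- array(as.integer(mask), d)
  n <- 0L
  for (ax in 1:3) {
    dm <- apply(m, setdiff(1:3, ax), function(v) sum(abs(diff(v))) + v[1] + v[length(v)])
    n <- n + sum(dm)
  }
  n
}

# A smooth random blob: thresholded, lightly smoothed white noise, largest
# 6-connected component retained. Deterministic given seed.
r_random_blob <- function(n = 40L, seed = 1L, q = 0.75) {
  set.seed(seed)
  f <- array(rnorm(n^3), c(n, n, n))
  # enough separable 3-tap passes (sigma ~ 3 voxels) that the blob surface
  # is smooth at the voxel scale, the regime where the 3/2 orientation
  # factor for face counting applies
  for (rep in 1:14) {
    f <- (f + f[c(1, 1:(n - 1)), , ] + f[c(2:n, n), , ]) / 3
    f <- (f + f[, c(1, 1:(n - 1)), ] + f[, c(2:n, n), ]) / 3
    f <- (f + f[, , c(1, 1:(n - 1))] + f[, , c(2:n, n)]) / 3
  }
  b <- f > quantile(f, q)
  b[c(1, 2, n - 1, n), , ] <- FALSE
  b[, c(1, 2, n - 1, n), ] <- FALSE
  b[, , c(1, 2, n - 1, n)] <- FALSE
  lab <- r_flood_label6(b)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  lab == keep
}

# Build a phantom object around an arbitrary label array (unit-tested
# plumbing shortcut; truth optional).
as_phantom <- function(labels, voxel_size = 2, with_truth = FALSE) {
  p <- structure(list(labels = labels, voxel_size = voxel_size,
                      seed = 0L, shape = "custom", size_params = NULL,
                      porosity = 0, truth = NULL),
                 class = "phantom")
  if (with_truth) p$truth <- compute_morphometry(p)
  p
}

# Voxelized ball mask centered in an n^3 grid.
r_ball <- function(n, r, ctr = (n + 1) / 2) {
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2, c(n, n, n))
}
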