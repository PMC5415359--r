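# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: distances by explicit 27-image enumeration,
# superposition by quaternion grid search, interval detection by a naive
# scan.

# minimum-image distance by brute force over all 27 periodic image shifts
# (points are wrapped into the primary cell first, as the convention
# requires)
oracle_min_image <- function(a, b, box) {
  a <- a - box * floor(a / box)
  b <- b - box * floor(b / box)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sum(d * d))
  }
  sqrt(best)
}

# exhaustive pairwise minimum distance (27-image per pair)
oracle_min_pair <- function(A, B, box = NULL) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    best <- min(best, if (is.null(box)) sqrt(sum((A[i, ] - B[j, ])^2))
                else oracle_min_image(A[i, ], B[j, ], box))
  }
  best
}

# quaternion -> rotation matrix
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# brute-force minimum RMSD over a hierarchically refined quaternion grid.
# Uses ||P R - Q||^2 = ||P||^2 + ||Q||^2 - 2 sum(R * (P^T Q)) on centred
# coordinates, so millions of grid rotations are cheap; no SVD anywhere.
oracle_grid_rmsd <- function(P, Q, n_coarse = 50000, n_refine = 800,
                             levels = 18) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  const <- sum(P^2) + sum(Q^2)
  n <- nrow(P)
  score <- function(qs) { # rows = quaternions
    qs <- qs / sqrt(rowSums(qs^2))
    w <- qs[, 1]; x <- qs[, 2]; y <- qs[, 3]; z <- qs[, 4]
    tr <- (1 - 2 * (y^2 + z^2)) * M[1, 1] + 2 * (x * y + w * z) * M[2, 1] +
      2 * (x * z - w * y) * M[3, 1] + 2 * (x * y - w * z) * M[1, 2] +
      (1 - 2 * (x^2 + z^2)) * M[2, 2] + 2 * (y * z + w * x) * M[3, 2] +
      2 * (x * z + w * y) * M[1, 3] + 2 * (y * z - w * x) * M[2, 3] +
      (1 - 2 * (x^2 + y^2)) * M[3, 3]
    const - 2 * tr
  }
  qs <- matrix(rnorm(4 * n_coarse), ncol = 4)
  ss <- score(qs)
  best <- qs[which.min(ss), ] / sqrt(sum(qs[which.min(ss), ]^2))
  best_s <- min(ss)
  delta <- 0.3
  for (l in seq_len(levels)) {
    cand <- matrix(rnorm(4 * n_refine, 0, delta), ncol = 4)
    cand <- sweep(cand, 2, best, "+")
    ss <- score(cand)
    if (min(ss) < best_s) {
      best_s <- min(ss)
      best <- cand[which.min(ss), ] / sqrt(sum(cand[which.min(ss), ]^2))
    }
    delta <- delta * 0.5
  }
  sqrt(max(best_s, 0) / n)
}

# naive interval scan: maximal runs of TRUE lasting >= min_duration
oracle_dry_intervals <- function(dry, min_duration) {
  out <- NULL
  i <- 1L; n <- length(dry)
  while (i <= n) {
    if (dry[i]) {
      j <- i
      while (j < n && dry[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_duration) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# analytic union area of two equal circles (lens formula)
oracle_two_circle_union <- function(r, d) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}
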