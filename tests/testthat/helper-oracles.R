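# Independent brute-force oracles used to verify the implementation paths.
# These deliberately avoid the package's own algorithms.

# Double-loop binary erosion: pixel survives iff every in-element neighbour
# (Euclidean disk, outside image = background) is TRUE.
oracle_erode <- function(mask, radius) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  r <- ceiling(radius)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ok <- TRUE
      for (di in -r:r) {
        for (dj in -r:r) {
          if (sqrt(di^2 + dj^2) > radius) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > H || jj < 1 || jj > W || !mask[ii, jj]) {
            ok <- FALSE
          }
        }
      }
      out[i, j] <- ok
    }
  }
  out
}

# Lattice-point enumeration: count of pixel centers within d/2 of center.
oracle_circle_count <- function(center, diameter, H, W) {
  n <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (sqrt((i - center[1])^2 + (j - center[2])^2) <= diameter / 2) {
        n <- n + 1L
      }
    }
  }
  n
}

# Recursive flood fill (8-connectivity) returning sizes and a label matrix.
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (si in seq_len(H)) {
    for (sj in seq_len(W)) {
      if (!mask[si, sj] || lab[si, sj] > 0L) next
      cur <- cur + 1L
      stack <- list(c(si, sj))
      lab[si, sj] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive 256-level between-class-variance scan (Otsu oracle) over the
# observed range; returns the threshold value maximizing the criterion.
oracle_otsu <- function(x, levels = 256) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- hist(x, breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1] + edges[-(levels + 1)]) / 2
  n <- sum(h)
  best <- -Inf; best_t <- centers[1]
  for (t in seq_len(levels - 1)) {
    w0 <- sum(h[1:t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * centers[1:t]) / w0
    m1 <- sum(h[(t + 1):levels] * centers[(t + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- (centers[t] + centers[t + 1]) / 2 }
  }
  best_t
}

# O(N^3) Kennard-Stone: recompute all pairwise distances at every step.
oracle_kennard_stone <- function(X, fraction) {
  N <- nrow(X)
  D <- as.matrix(dist(X))
  n_train <- max(2L, min(N, as.integer(round(fraction * N))))
  start <- which(D == max(D), arr.ind = TRUE)
  pair <- sort(unname(start[1, 1:2]))
  sel <- pair
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(N), sel)
    mind <- sapply(rest, function(i) min(D[i, sel]))
    sel <- c(sel, rest[which.max(mind)])
  }
  list(train_idx = sel, val_idx = setdiff(seq_len(N), sel))
}

# Local least-squares Savitzky-Golay coefficients from the normal equations.
oracle_sg_central_coefs <- function(window, order) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:order, `^`)
  H <- solve(crossprod(A), t(A))
  H[1, ]  # evaluation at the window center
}

# 90-degree counter-clockwise rotation of a matrix.
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]
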