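# Independent oracles used across the suite. Each deliberately re-derives
# the quantity from its definition, by brute force where possible, so the
# implementation under test is never on both sides of an assertion.

# Per-pixel 3x3 median with reflected edges, computed pixel by pixel.
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(i, n) pmin(pmax(i, 1L), n)
  out <- m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      neigh <- numeric(9)
      k <- 0L
      for (dr in -1:1) {
        for (dc in -1:1) {
          k <- k + 1L
          neigh[k] <- m[reflect(r + dr, nr), reflect(c + dc, nc)]
        }
      }
      out[r, c] <- median(neigh)
    }
  }
  out
}

# Exhaustive between-class-variance threshold search over every candidate
# level below the maximum.
oracle_otsu <- function(gray) {
  vals <- sort(unique(as.vector(gray)))
  cand <- vals[-length(vals)]
  best <- -Inf; thr <- cand[1]
  for (tt in cand) {
    lo <- gray[gray <= tt]; hi <- gray[gray > tt]
    w0 <- length(lo) / length(gray); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best + 1e-15) {
      best <- bc; thr <- tt
    }
  }
  thr
}

# Absolute Pearson correlation straight from the product-moment definition.
oracle_pearson_abs <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  abs(sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)))
}

# Minimum enclosing rectangle by brute force over a fine grid of
# orientations applied to the pixel-square corner set.
oracle_min_rect_sides <- function(binary, n_angles = 3600) {
  px <- which(binary, arr.ind = TRUE)
  corners <- rbind(
    cbind(px[, 1] - 0.5, px[, 2] - 0.5), cbind(px[, 1] - 0.5, px[, 2] + 0.5),
    cbind(px[, 1] + 0.5, px[, 2] - 0.5), cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  best <- NULL
  for (a in seq(0, pi / 2, length.out = n_angles)) {
    rot <- cbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    pts <- corners %*% rot
    w <- diff(range(pts[, 1])); h <- diff(range(pts[, 2]))
    if (is.null(best) || w * h < best$area) best <- list(area = w * h, sides = sort(c(w, h)))
  }
  best$sides
}

# Filled disk of radius r centred in an n x n logical grid.
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

# Count of strict local maxima at or above a height floor.
oracle_count_peaks <- function(x, min_height) {
  p <- pracma::findpeaks(x, minpeakheight = min_height)
  if (is.null(p)) 0L else nrow(p)
}
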