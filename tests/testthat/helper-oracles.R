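# Independent brute-force oracles. These deliberately use the plainest
# possible formulation (per-pixel loops, exhaustive enumeration) and share no
# code with the implementation paths they check.

# Even-odd point-in-polygon test for a single point.
bf_point_in_polygon <- function(px, py, v) {
  inside <- FALSE
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    if ((y1 > py) != (y2 > py)) {
      xc <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xc) inside <- !inside
    }
    j <- i
  }
  inside
}

bf_rasterize <- function(v, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (row in seq_len(shape[1])) {
    for (col in seq_len(shape[2])) {
      out[row, col] <- bf_point_in_polygon(col - 1, row - 1, v)
    }
  }
  out
}

# Dilation by distance threshold: pixel is set iff some mask pixel lies
# within distance r under the given metric.
bf_dilate <- function(mask, r, metric) {
  nr <- nrow(mask); nc <- ncol(mask)
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0) return(mask)
  out <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(src))) {
    dr <- abs(rows - src[k, 1]); dc <- abs(cols - src[k, 2])
    d <- if (metric == "chebyshev") pmax(dr, dc) else sqrt(dr^2 + dc^2)
    out <- out | (d <= r)
  }
  out
}

bf_manders <- function(p1, p2, t1, t2, roi_mask) {
  num1 <- 0; den1 <- 0; num2 <- 0; den2 <- 0
  for (i in seq_along(p1)) {
    if (!roi_mask[i]) next
    den1 <- den1 + p1[i]; den2 <- den2 + p2[i]
    if (p2[i] > t2) num1 <- num1 + p1[i]
    if (p1[i] > t1) num2 <- num2 + p2[i]
  }
  list(tM1 = if (den1 > 0) num1 / den1 else NA_real_,
       tM2 = if (den2 > 0) num2 / den2 else NA_real_)
}

# Exhaustive threshold search: among all distinct ch1 values (descending),
# the largest T1 whose below-threshold pixel set (both channels below the
# linked pair) has >= 10 pairs, non-degenerate variance, and Pearson r <= 0.
# The scan mirrors the documented stopping semantics without sharing any
# early-exit shortcuts with the implementation.
bf_costes_threshold <- function(x, y, slope, intercept) {
  cand <- sort(unique(x), decreasing = TRUE)
  for (t1 in cand) {
    sel <- x < t1 & y < slope * t1 + intercept
    if (sum(sel) < 10) {
      return(list(threshold_ch1 = t1, converged = FALSE))
    }
    xb <- x[sel]; yb <- y[sel]
    if (var(xb) == 0 || var(yb) == 0) {
      return(list(threshold_ch1 = t1, converged = FALSE))
    }
    if (cor(xb, yb) <= 0) {
      return(list(threshold_ch1 = t1, converged = TRUE))
    }
  }
  list(threshold_ch1 = min(cand), converged = FALSE)
}

# Closed-form simple linear regression (normal equations) plus Pearson r.
bf_linear_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}
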