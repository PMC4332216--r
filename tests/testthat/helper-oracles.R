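# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths than the package implementation.

# Pure-R projection-variance objective: project each pixel of a
# mean-subtracted block onto the axis perpendicular to the candidate streak
# direction, bin at unit width, and return the count-weighted variance of
# the bin means. Same mathematical definition as the compiled scanner,
# written independently (vectorized R, no shared code).
r_projection_variance <- function(block, angles_deg) {
  nr <- nrow(block); nc <- ncol(block)
  ii <- rep(seq_len(nr) - 1L, times = nc)   # row index, 0-based
  jj <- rep(seq_len(nc) - 1L, each = nr)    # col index, 0-based
  vals <- as.numeric(block)                 # column-major, matches ii/jj
  vapply(angles_deg, function(th) {
    thr <- th * pi / 180
    u <- jj * cos(thr) - ii * sin(thr)
    b <- round(u - min(u)) + 1L
    sums <- tapply(vals, b, sum)
    cnts <- tapply(vals, b, length)
    m <- sums / cnts
    mbar <- sum(sums) / length(vals)
    sum(cnts * (m - mbar)^2) / length(vals)
  }, numeric(1))
}

# Exhaustive streak-angle search: a dense global grid followed by an
# exhaustive 0.001-degree sweep around the global-grid maximum.
exhaustive_radon_angle <- function(block, global_step = 0.2,
                                   local_halfwidth = 0.3) {
  b <- block - mean(block)
  g1 <- seq(-89, 89, by = global_step)
  v1 <- radon_angle_scan(b, g1)
  t1 <- g1[which.max(v1)]
  g2 <- seq(t1 - local_halfwidth, t1 + local_halfwidth, by = 0.001)
  g2 <- g2[abs(g2) < 89.999]
  v2 <- radon_angle_scan(b, g2)
  g2[which.max(v2)]
}

# Closed-form ordinary-least-squares solution from the normal equations.
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Intensity-weighted centroid of the darkest streak on one kymograph row,
# within +/- halfwidth pixels of the row minimum.
streak_centroid <- function(img, row, halfwidth = 12) {
  line <- img[row, ]
  j0 <- which.min(line)
  jj <- max(1, j0 - halfwidth):min(ncol(img), j0 + halfwidth)
  wgt <- max(line) - line[jj]
  sum(jj * wgt) / sum(wgt)
}

# Full discrete cross-correlogram argmax (integer-lag oracle for the
# correlation velocimeter).
discrete_correlogram_peak <- function(block, line_lag = 1L) {
  nr <- nrow(block); nc <- ncol(block)
  rows <- sweep(block, 1, rowMeans(block))
  A <- rows[seq_len(nr - line_lag), , drop = FALSE]
  B <- rows[(1L + line_lag):nr, , drop = FALSE]
  lags <- seq.int(-floor(nc / 2), floor(nc / 2))
  cg <- vapply(lags, function(s) {
    if (s >= 0) sum(A[, seq_len(nc - s), drop = FALSE] *
                      B[, (1L + s):nc, drop = FALSE]) / (nc - s)
    else sum(A[, (1L - s):nc, drop = FALSE] *
               B[, seq_len(nc + s), drop = FALSE]) / (nc + s)
  }, numeric(1))
  lags[which.max(cg)]
}
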