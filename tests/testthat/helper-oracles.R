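# Independent oracles used to check the analytical fits against brute
# force or closed forms.

# Closed-form simple OLS: slope = S_xy / S_xx, line through the centroid.
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

orth_sse <- function(x, y, intercept, slope) {
  sum((y - intercept - slope * x)^2) / (1 + slope^2)
}

# Brute-force orthogonal regression: coarse angle sweep through the
# centroid, then a 201 x 201 slope/intercept grid around the sweep
# optimum. Returns the grid minimiser and the grid resolutions.
deming_grid_oracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  theta <- seq(-pi / 2 + 1e-3, pi / 2 - 1e-3, length.out = 2001)
  sse <- vapply(theta, function(th) {
    b <- tan(th)
    orth_sse(x, y, yb - b * xb, b)
  }, numeric(1))
  b0 <- tan(theta[which.min(sse)])
  a0 <- yb - b0 * xb
  db <- max(abs(b0) * 0.05, 0.02)
  da <- max(abs(a0) * 0.05, 0.05 * stats::sd(y), 0.02)
  slopes <- seq(b0 - db, b0 + db, length.out = 201)
  ints <- seq(a0 - da, a0 + da, length.out = 201)
  grid_sse <- outer(ints, slopes, function(a, b) {
    mapply(function(ai, bi) orth_sse(x, y, ai, bi), a, b)
  })
  k <- arrayInd(which.min(grid_sse), dim(grid_sse))
  list(intercept = ints[k[1]], slope = slopes[k[2]],
       slope_step = diff(slopes[1:2]), intercept_step = diff(ints[1:2]),
       sse = min(grid_sse))
}

# Random (mouse, day) endpoint tables for decomposition identity checks.
random_fits_table <- function(n_days, mouse = "m1") {
  tibble::tibble(
    mouse = mouse,
    day = seq_len(n_days),
    start_est = stats::runif(n_days, 0, 300),
    end_est = stats::runif(n_days, 0, 300)
  )
}
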