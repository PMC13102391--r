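as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    points <- data.frame(x = points[, 1], y = points[, 2])
  }
  if (!all(c("x", "y") %in% names(points))) {
    stop("points must have columns x and y", call. = FALSE)
  }
  points[c("x", "y")]
}

deming_slope <- function(x, y, delta) {
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (!is.finite(sxy) || sxy == 0) {
    stop("degenerate fit: sample covariance of x and y is zero",
         call. = FALSE)
  }
  a <- syy - delta * sxx
  slope <- (a + sqrt(a^2 + 4 * delta * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Equal-variance Deming (orthogonal) regression with bootstrap CIs
#'
#' Errors-in-variables straight-line fit for data in which x and y carry
#' random noise of equal variance (`delta = 1`), as is the case when both
#' coordinates derive from the same latency measurements. The slope is
#' the closed-form minimiser of the total squared orthogonal distance,
#' \deqn{b = \frac{(s_{yy} - \delta s_{xx}) +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4\delta s_{xy}^2}}{2 s_{xy}},}
#' with the intercept constrained through the centroid. 95% confidence
#' intervals are obtained by a seeded nonparametric bootstrap: points are
#' resampled i.i.d. with replacement and percentile intervals taken over
#' the resampled slopes and intercepts.
#'
#' @param points Data frame (or 2-column matrix) with columns `x`, `y`;
#'   at least 3 points with non-zero covariance.
#' @param delta Ratio of y-error variance to x-error variance; fixed at 1
#'   (equal variance) in all package analyses and exposed for testing.
#' @param n_boot Bootstrap resamples for the CIs (default 1000; 0 skips
#'   the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param conf Confidence level of the percentile intervals.
#' @return Object of class `deming_fit`: `slope`, `intercept`, `delta`,
#'   `n_points`, `slope_ci`, `intercept_ci`, `n_boot`, `seed`, and the
#'   fit centroid `x_mean`, `y_mean`.
#' @examples
#' pts <- data.frame(x = c(0, 1, 2, 3), y = c(0, 2, 3, 5))
#' deming_fit(pts, n_boot = 200, seed = 1)
#' @export
deming_fit <- function(points, delta = 1, n_boot = 1000, seed = 1L,
                       conf = 0.95) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 3) stop("Deming regression needs at least 3 points", call. = FALSE)
  est <- deming_slope(pts$x, pts$y, delta)

  slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  n_boot_used <- 0L
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(deming_slope(pts$x[idx], pts$y[idx], delta),
                 error = function(e) c(slope = NA_real_,
                                       intercept = NA_real_))
      }, numeric(2))
    })
    ok <- !is.na(boots[1, ])
    n_boot_used <- sum(ok)
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    if (n_boot_used > 0) {
      slope_ci <- unname(stats::quantile(boots[1, ok], probs))
      intercept_ci <- unname(stats::quantile(boots[2, ok], probs))
    }
  }
  structure(list(
    slope = unname(est["slope"]), intercept = unname(est["intercept"]),
    delta = delta, n_points = n,
    slope_ci = slope_ci, intercept_ci = intercept_ci,
    n_boot = n_boot_used, seed = seed, conf = conf,
    x_mean = mean(pts$x), y_mean = mean(pts$y)
  ), class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (delta = %g, n = %d)\n", x$delta,
              x$n_points))
  cat(sprintf("  slope     %8.4f  [%s]\n", x$slope,
              paste(sprintf("%.4f", x$slope_ci), collapse = ", ")))
  cat(sprintf("  intercept %8.4f  [%s]\n", x$intercept,
              paste(sprintf("%.4f", x$intercept_ci), collapse = ", ")))
  if (x$n_boot > 0) {
    cat(sprintf("  %d bootstrap resamples, %g%% percentile CIs, seed %d\n",
                x$n_boot, 100 * x$conf, x$seed))
  }
  invisible(x)
}

#' Signed orthogonal residuals to a Deming line
#'
#' Perpendicular (shortest) distance of each point to the fitted line,
#' signed positive above the line:
#' `r = (y - intercept - slope * x) / sqrt(1 + slope^2)`.
#'
#' @param points Data frame or matrix with columns `x`, `y`.
#' @param fit A [deming_fit()] object (or any list with `slope` and
#'   `intercept`).
#' @return Numeric vector of signed distances (same units as y).
#' @export
signed_residuals <- function(points, fit) {
  pts <- as_xy(points)
  if (!is.finite(fit$slope)) stop("fit slope is not finite", call. = FALSE)
  (pts$y - fit$intercept - fit$slope * pts$x) / sqrt(1 + fit$slope^2)
}

#' Compare a treatment group to the control regression line
#'
#' Fits the equal-variance Deming line on the control points only, then
#' compares the signed orthogonal residuals of treatment and control
#' points about that line with a two-sided unpaired Wilcoxon rank-sum
#' test. A treatment median residual below the control's indicates that
#' the treated relationship sits below the control line (e.g. less
#' learning for the same initial performance, or less consolidation for
#' the same learning).
#'
#' The test is exact when both groups have at most 12 points and the
#' residuals are tie-free; otherwise the tie-corrected normal
#' approximation is used. Each (mouse, day) point is treated as
#' independent, as in the scatter it summarises; see the package vignette
#' for the pseudo-replication caveat.
#'
#' @param control_points,treatment_points Data frames with columns `x`,
#'   `y` (e.g. rows of [phase_scatter()] for each group).
#' @inheritParams deming_fit
#' @return Object of class `group_comparison`: `fit` (control
#'   [deming_fit()]) and `test`, a list with the rank statistic `W`,
#'   two-sided `p_value`, group medians, `median_difference`
#'   (treatment - control), a `direction` label, sample sizes, and both
#'   residual vectors.
#' @export
compare_groups <- function(control_points, treatment_points, delta = 1,
                           n_boot = 1000, seed = 1L) {
  ctrl <- as_xy(control_points)
  trt <- as_xy(treatment_points)
  if (nrow(trt) < 1) stop("treatment group is empty", call. = FALSE)
  fit <- deming_fit(ctrl, delta = delta, n_boot = n_boot, seed = seed)
  res_c <- signed_residuals(ctrl, fit)
  res_t <- signed_residuals(trt, fit)
  exact <- min(length(res_c), length(res_t)) <= 12 &&
    !anyDuplicated(c(res_c, res_t))
  wt <- suppressWarnings(
    stats::wilcox.test(res_t, res_c, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  md <- stats::median(res_t) - stats::median(res_c)
  test <- list(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    median_control = stats::median(res_c),
    median_treatment = stats::median(res_t),
    median_difference = md,
    direction = if (md < 0) "treatment_below" else if (md > 0)
      "treatment_above" else "no_shift",
    n_control = length(res_c),
    n_treatment = length(res_t),
    control_residuals = res_c,
    treatment_residuals = res_t
  )
  structure(list(fit = fit, test = test), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$fit)
  t <- x$test
  cat(sprintf("Residual rank test (n_control = %d, n_treatment = %d)\n",
              t$n_control, t$n_treatment))
  cat(sprintf("  W = %.1f, two-sided p = %.4g\n", t$statistic, t$p_value))
  cat(sprintf("  median residuals: control %.3f, treatment %.3f (%s)\n",
              t$median_control, t$median_treatment, t$direction))
  invisible(x)
}

#' Bivariate-normal probability ellipse of a scatter
#'
#' Fits a bivariate normal by maximum likelihood (mean and covariance
#' with divisor n) and returns the contour enclosing a given probability
#' mass: the set of points at squared Mahalanobis distance equal to the
#' corresponding chi-squared (2 df) quantile.
#'
#' @param points Data frame or matrix with columns `x`, `y`; at least 3
#'   points with non-singular covariance.
#' @param mass Probability mass enclosed by the contour (default 0.5).
#' @return Object of class `ellipse_summary`: `center`, `cov` (MLE),
#'   `radii` (half-axis lengths, decreasing), `angle_deg` (orientation of
#'   the major axis, degrees counter-clockwise from +x), `mass`, `n`.
#' @export
ellipse_summary <- function(points, mass = 0.5) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 3) stop("ellipse summary needs at least 3 points", call. = FALSE)
  stopifnot(mass > 0, mass < 1)
  center <- c(x = mean(pts$x), y = mean(pts$y))
  centred <- cbind(pts$x - center[1], pts$y - center[2])
  sigma <- crossprod(centred) / n
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-12 || max(ev$values) == 0) {
    stop("singular covariance: points are (near) collinear", call. = FALSE)
  }
  r2 <- stats::qchisq(mass, df = 2)
  structure(list(
    center = center, cov = sigma,
    radii = sqrt(ev$values * r2),
    angle_deg = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi,
    mass = mass, n = n
  ), class = "ellipse_summary")
}

#' Contour coordinates of a probability ellipse
#'
#' @param e An [ellipse_summary()] object.
#' @param n_points Number of polygon vertices.
#' @return Tibble with columns `x`, `y` tracing the contour.
#' @export
ellipse_coords <- function(e, n_points = 180) {
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  phi <- e$angle_deg * pi / 180
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  unit <- rbind(e$radii[1] * cos(theta), e$radii[2] * sin(theta))
  xy <- t(rot %*% unit)
  tibble::tibble(x = xy[, 1] + e$center[1], y = xy[, 2] + e$center[2])
}
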