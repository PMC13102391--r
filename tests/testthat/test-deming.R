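test_that("exact linear data is fit exactly, with zero residual spread", {
  pts <- data.frame(x = 0:5, y = 2 * (0:5) + 1)
  fit <- deming_fit(pts, n_boot = 0)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(signed_residuals(pts, fit), rep(0, 6), tolerance = 1e-12)
})

test_that("orthogonal regression is symmetric under swapping axes", {
  set.seed(1)
  x <- rnorm(30)
  y <- 1.7 * x + rnorm(30, sd = 0.5)
  f1 <- deming_fit(data.frame(x = x, y = y), n_boot = 0)
  f2 <- deming_fit(data.frame(x = y, y = x), n_boot = 0)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-10)
})

test_that("the four-point fit matches the frozen closed form", {
  pts <- data.frame(x = 0:3, y = c(0, 2, 3, 5))
  fit <- deming_fit(pts, n_boot = 0)
  # slope (8 + sqrt(320)) / 16, intercept through the centroid
  expect_equal(fit$slope, (8 + sqrt(320)) / 16, tolerance = 1e-12)
  expect_equal(fit$slope, 1.618034, tolerance = 1e-6)
  expect_equal(fit$intercept, 2.5 - fit$slope * 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.072949, tolerance = 1e-5)
})

test_that("closed-form fit matches brute-force orthogonal-SSE search", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- runif(n, -2, 2)
    y <- runif(1, -2, 2) * x + rnorm(n, sd = 0.4) + runif(1, -1, 1)
    if (abs(stats::cov(x, y)) < 0.05) next
    fit <- deming_fit(data.frame(x = x, y = y), n_boot = 0)
    o <- deming_grid_oracle(x, y)
    expect_lt(abs(fit$slope - o$slope), o$slope_step)
    expect_lt(abs(fit$intercept - o$intercept), 2 * o$intercept_step)
    # the closed form is never beaten by any grid line
    expect_lte(orth_sse(x, y, fit$intercept, fit$slope),
               o$sse + 1e-9)
  }
})

test_that("slope is scale-invariant and translation-equivariant", {
  set.seed(3)
  pts <- data.frame(x = runif(25, 0, 10))
  pts$y <- 1.4 * pts$x + rnorm(25)
  f <- deming_fit(pts, n_boot = 0)
  f_scaled <- deming_fit(transform(pts, x = 3 * x, y = 3 * y),
                         n_boot = 0)
  expect_equal(f_scaled$slope, f$slope, tolerance = 1e-12)
  f_shift <- deming_fit(transform(pts, x = x + 5, y = y - 2), n_boot = 0)
  expect_equal(f_shift$slope, f$slope, tolerance = 1e-10)
  expect_equal(f_shift$intercept, f$intercept - 2 - f$slope * 5,
               tolerance = 1e-10)
})

test_that("signed residuals follow the perpendicular-distance convention", {
  line <- list(slope = 1, intercept = 0)
  expect_equal(signed_residuals(data.frame(x = 2, y = 2), line), 0)
  expect_equal(signed_residuals(data.frame(x = 1, y = 0), line),
               -1 / sqrt(2))
  expect_equal(signed_residuals(data.frame(x = 0, y = 1), line),
               1 / sqrt(2))
})

test_that("signed residuals of the fitting points sum to zero", {
  set.seed(12)
  for (i in 1:10) {
    pts <- data.frame(x = rnorm(20), y = rnorm(20) + 0.8 * rnorm(20))
    fit <- deming_fit(pts, n_boot = 0)
    expect_equal(sum(signed_residuals(pts, fit)), 0, tolerance = 1e-9)
  }
})

test_that("degenerate geometry is refused", {
  expect_error(deming_fit(data.frame(x = c(0, 1), y = c(0, 1))),
               "at least 3")
  cross <- data.frame(x = c(0, 0, 1, -1), y = c(1, -1, 0, 0))
  expect_error(deming_fit(cross), "degenerate")
  expect_error(deming_fit(data.frame(x = rep(2, 5), y = 1:5)),
               "degenerate")
})

test_that("bootstrap CIs bracket the estimate and tighten with n", {
  gen <- function(n, seed) {
    with(list(), {
      set.seed(seed)
      x <- runif(n, 0, 10)
      data.frame(x = x, y = 2 + 1.3 * x + rnorm(n))
    })
  }
  f_small <- deming_fit(gen(40, 1), n_boot = 400, seed = 2)
  f_big <- deming_fit(gen(400, 1), n_boot = 400, seed = 2)
  for (f in list(f_small, f_big)) {
    expect_lte(f$slope_ci[1], f$slope)
    expect_gte(f$slope_ci[2], f$slope)
    expect_lte(f$intercept_ci[1], f$intercept)
    expect_gte(f$intercept_ci[2], f$intercept)
  }
  expect_lt(diff(f_big$slope_ci), diff(f_small$slope_ci))
  # seeded: identical on re-run
  expect_identical(deming_fit(gen(40, 1), n_boot = 400, seed = 2)[
    c("slope_ci", "intercept_ci")],
    f_small[c("slope_ci", "intercept_ci")])
})

test_that("identical groups give the null rank statistic", {
  set.seed(5)
  pts <- data.frame(x = runif(12, 0, 10))
  pts$y <- pts$x + rnorm(12, sd = 0.3)
  cmp <- compare_groups(pts, pts, n_boot = 0)
  expect_equal(cmp$test$statistic, 12 * 12 / 2)
  expect_gte(cmp$test$p_value, 0.99)
  expect_equal(cmp$test$median_difference, 0)
})

test_that("a vertical shift fully separates the residual distributions", {
  ctrl <- data.frame(x = seq(0, 10, length.out = 20))
  ctrl$y <- ctrl$x
  trt <- transform(ctrl, y = y - 20)
  cmp <- compare_groups(ctrl, trt, n_boot = 0)
  expect_equal(cmp$test$median_difference, -20 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(cmp$test$statistic, 0)
  expect_lt(cmp$test$p_value, 0.001)
  expect_equal(cmp$test$direction, "treatment_below")
})

test_that("offline-consolidation deficit is detected in the designed comparison", {
  # majority vote over seeded replicates of the generator scenario
  hits_consol <- hits_init <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    p <- scenario_pvalues("offline_consolidation_deficit", seed = s)
    hits_consol <- hits_consol + (p["consol"] < 0.01)
    hits_init <- hits_init + (p["init"] < 0.05)
  }
  expect_gt(hits_consol, n_rep / 2)
  expect_lt(hits_init, n_rep / 2)
})

test_that("probability ellipse matches the chi-squared contour", {
  set.seed(31)
  iso <- data.frame(x = rnorm(20000), y = rnorm(20000))
  e <- ellipse_summary(iso, mass = 0.5)
  expect_equal(unname(e$radii), rep(sqrt(qchisq(0.5, 2)), 2),
               tolerance = 0.03)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.03)

  flat <- data.frame(x = 1:5, y = rep(2, 5))
  expect_error(ellipse_summary(flat), "singular")
})

test_that("the 50% ellipse encloses half of the fitted normal's mass", {
  skip_if_not_installed("MASS")
  set.seed(17)
  pts <- data.frame(x = rnorm(200, sd = 2))
  pts$y <- 0.5 * pts$x + rnorm(200)
  e <- ellipse_summary(pts, mass = 0.5)
  draws <- MASS::mvrnorm(1e5, mu = e$center, Sigma = e$cov)
  d2 <- stats::mahalanobis(draws, e$center, e$cov)
  expect_equal(mean(d2 <= qchisq(0.5, 2)), 0.5, tolerance = 0.02)
  # and the polygon helper traces that contour
  ring <- ellipse_coords(e, 90)
  ring_d2 <- stats::mahalanobis(cbind(ring$x, ring$y), e$center, e$cov)
  expect_equal(ring_d2, rep(qchisq(0.5, 2), 90), tolerance = 1e-8)
})
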