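make_day <- function(latency, trial = seq_along(latency), mouse = "m1",
                     day = 1L) {
  tibble::tibble(mouse = mouse, day = day, trial = trial,
                 latency = latency)
}

test_that("daily regression reproduces exact and hand-computed lines", {
  # exact line
  f <- fit_daily_regression(make_day(seq(60, 120, by = 10)))
  expect_equal(f$slope, 10)
  expect_equal(f$start_est, 60)
  expect_equal(f$end_est, 120)

  # constant performance
  f <- fit_daily_regression(make_day(rep(100, 7)))
  expect_equal(f$slope, 0)
  expect_equal(f$start_est, 100)
  expect_equal(f$end_est, 100)

  # noisy day against the closed-form OLS oracle
  y <- c(50, 80, 60, 90, 100, 85, 110)
  f <- fit_daily_regression(make_day(y))
  o <- ols_oracle(1:7, y)
  expect_equal(f$slope, unname(o["slope"]))
  expect_equal(f$slope, 230 / 28, tolerance = 1e-12)
  expect_equal(f$start_est, 57.5, tolerance = 1e-10)
  expect_equal(f$end_est, 106.7857142857, tolerance = 1e-8)

  # invariants: endpoint difference and centroid pass-through
  expect_equal(f$end_est - f$start_est, f$slope * 6)
  expect_equal(f$intercept + f$slope * 4, mean(y))
})

test_that("daily regression rejects unusable mouse-days", {
  expect_error(fit_daily_regression(make_day(c(50, 60))), "at least 3")
  expect_error(fit_daily_regression(make_day(c(50, 60, 70),
                                             trial = c(1, 2, 2))),
               "duplicate")
  expect_error(fit_daily_regression(make_day(c(50, 60, 70),
                                             trial = c(1, 2, 9))),
               "1..trials_per_day")
  heavy <- make_day(c(100, 300, 300, 300, 300, 120, 130))
  heavy$censored <- heavy$latency == 300
  expect_warning(fit_daily_regression(heavy), "censored")
})

test_that("missing trials still give endpoints at indices 1 and 7", {
  f <- fit_daily_regression(make_day(c(60, 80, 100),
                                     trial = c(2, 4, 6)))
  expect_equal(f$slope, 10)
  expect_equal(f$start_est, 50)
  expect_equal(f$end_est, 110)
  expect_equal(f$n_trials_used, 3)
})

test_that("vectorised daily fits agree with the per-day regression", {
  sim <- simulate_cohort(cohort_params(n_mice_per_group = 3, seed = 2))
  f_vec <- daily_fits(sim$trials)
  parts <- split(sim$trials, list(sim$trials$mouse, sim$trials$day),
                 drop = TRUE)
  f_ref <- dplyr::bind_rows(lapply(parts, fit_daily_regression))
  f_ref <- f_ref[order(f_ref$mouse, f_ref$day), ]
  for (col in c("slope", "intercept", "start_est", "end_est")) {
    expect_equal(f_vec[[col]], f_ref[[col]], tolerance = 1e-10)
  }
  expect_equal(f_vec$n_censored, f_ref$n_censored)
  # and the vectorised metrics agree with the per-mouse decomposition
  m_vec <- learning_metrics(f_vec)
  m_ref <- dplyr::bind_rows(lapply(split(f_vec, f_vec$mouse),
                                   decompose_mouse))
  expect_equal(as.data.frame(m_vec), as.data.frame(m_ref))
})

test_that("decomposition reproduces the day/night arrows", {
  fits <- tibble::tibble(mouse = "m1", day = 1:2,
                         start_est = c(60, 120), end_est = c(120, 150))
  m <- decompose_mouse(fits)
  expect_equal(m$within_day[1], 60)
  expect_equal(m$overnight[1], 0)
  expect_equal(m$consolidated[1], 60)
  expect_true(is.na(m$overnight[2]) && is.na(m$consolidated[2]))

  # full overnight loss
  fits$start_est[2] <- 60
  m <- decompose_mouse(fits)
  expect_equal(m$overnight[1], -60)
  expect_equal(m$consolidated[1], 0)
})

test_that("consolidated equals within-day plus overnight on random tables", {
  set.seed(42)
  for (i in 1:50) {
    fits <- random_fits_table(sample(3:9, 1))
    m <- decompose_mouse(fits)
    ok <- !is.na(m$overnight)
    expect_equal(m$consolidated[ok], m$within_day[ok] + m$overnight[ok],
                 tolerance = 1e-12)
  }
})

test_that("day gaps suppress the affected overnight transitions", {
  fits <- tibble::tibble(mouse = "m1", day = c(1L, 2L, 4L, 5L),
                         start_est = c(60, 90, 140, 160),
                         end_est = c(80, 120, 150, 170))
  m <- decompose_mouse(fits)
  expect_false(is.na(m$overnight[1]))
  expect_true(is.na(m$overnight[m$day == 2]))   # day 3 absent
  expect_false(is.na(m$overnight[m$day == 4]))
  expect_error(decompose_mouse(fits[c(2, 1, 3, 4), ]), "ordered")
})

test_that("phase scatters count mice x eligible days", {
  sim <- simulate_cohort(cohort_params(n_mice_per_group = 5, seed = 8))
  m <- learning_metrics(daily_fits(sim$trials))
  ctrl <- m[m$group == "control", ]
  expect_equal(nrow(phase_scatter(ctrl, "init_vs_learning", "early")), 20)
  expect_equal(nrow(phase_scatter(ctrl, "learning_vs_consolidated",
                                  "early")), 15)
  expect_equal(nrow(phase_scatter(ctrl, "init_vs_learning", "late")), 15)
  expect_equal(nrow(phase_scatter(ctrl, "learning_vs_consolidated",
                                  "late")), 10)

  # a missing day removes both adjacent nights for that mouse
  one <- daily_fits(sim$trials[sim$trials$mouse == "control_01" &
                                 sim$trials$day != 3, ])
  m1 <- learning_metrics(one)
  sc <- phase_scatter(m1, "learning_vs_consolidated", "early")
  expect_setequal(sc$day, 1)
  expect_error(phase_scatter(m1[0, ], "init_vs_learning", "early"),
               "no points")
})

test_that("regression endpoints recover noise-free latent skill", {
  p <- cohort_params(n_mice_per_group = 4, trial_sd = 0, s0_sd = 12,
                     seed = 6)
  sim <- simulate_cohort(p)
  fits <- daily_fits(sim$trials)
  merged <- merge(fits, sim$latent, by = c("mouse", "day"))
  expect_equal(merged$start_est, merged$s_start, tolerance = 1e-8)
  expect_equal(merged$end_est, merged$s_end, tolerance = 1e-8)
})

test_that("regression endpoints denoise relative to raw trial-1 latency", {
  p <- cohort_params(n_mice_per_group = 10, trial_sd = 25, seed = 21)
  sim <- simulate_cohort(p)
  fits <- daily_fits(sim$trials)
  merged <- merge(fits, sim$latent, by = c("mouse", "day"))
  raw1 <- sim$trials[sim$trials$trial == 1, ]
  raw <- merge(raw1, sim$latent, by = c("mouse", "day"))
  mae_fit <- mean(abs(merged$start_est - merged$s_start))
  mae_raw <- mean(abs(raw$latency - raw$s_start))
  expect_lt(mae_fit, mae_raw)
})

test_that("rotarod ramp arithmetic and its inverse agree", {
  expect_equal(rotarod_speed(0), 4)
  expect_equal(rotarod_speed(300), 40)
  expect_equal(time_to_speed(20), 400 / 3)
  t <- seq(0, 300, by = 7.5)
  expect_equal(time_to_speed(rotarod_speed(t)), t)
  expect_error(rotarod_speed(301), "300")
  expect_error(time_to_speed(3), "rpm")
})
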