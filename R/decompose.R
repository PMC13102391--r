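#' Daily linear regression of latency on trial index
#'
#' Fits ordinary least squares of latency against trial index for one
#' mouse-day and evaluates the fitted line at trial 1 and at trial
#' `trials_per_day`. These endpoint estimates are used as the day's
#' initial and final skill level: single-trial latencies are noisy, and
#' the regression endpoints denoise them. Censored (ceiling) trials enter
#' the regression as recorded; a warning is emitted when at least half
#' the day's trials are censored, since the fit then understates skill.
#'
#' @param trials Tibble/data.frame of one mouse-day with columns `trial`,
#'   `latency` (optionally `mouse`, `day`, `group`, `censored`).
#' @param trials_per_day Trial index at which the end-of-day skill is
#'   evaluated (default 7). Endpoints are always evaluated at indices 1
#'   and `trials_per_day`, even when some trials are missing.
#' @return One-row tibble: `mouse, group, day, slope, intercept,
#'   start_est, end_est, n_trials_used, n_censored`.
#' @examples
#' d <- data.frame(trial = 1:7, latency = c(60, 70, 80, 90, 100, 110, 120))
#' fit_daily_regression(d)
#' @export
fit_daily_regression <- function(trials, trials_per_day = 7) {
  trials <- trials[!is.na(trials$latency), , drop = FALSE]
  if (anyDuplicated(trials$trial)) {
    stop("duplicate trial indices within one mouse-day", call. = FALSE)
  }
  if (any(trials$trial < 1 | trials$trial > trials_per_day)) {
    stop("trial indices must lie within 1..trials_per_day", call. = FALSE)
  }
  if (nrow(trials) < 3) {
    stop("at least 3 trials are required for a daily regression",
         call. = FALSE)
  }
  n_censored <- if ("censored" %in% names(trials)) {
    sum(trials$censored, na.rm = TRUE)
  } else 0L
  if (n_censored >= nrow(trials) / 2) {
    warning("at least half of the trials are censored at the ceiling; ",
            "endpoint estimates are biased low", call. = FALSE)
  }
  fit <- stats::lm(latency ~ trial, data = trials)
  b <- stats::coef(fit)
  tibble::tibble(
    mouse = if ("mouse" %in% names(trials)) trials$mouse[1] else NA_character_,
    group = if ("group" %in% names(trials)) trials$group[1] else NA_character_,
    day = if ("day" %in% names(trials)) trials$day[1] else NA_integer_,
    slope = unname(b[2]),
    intercept = unname(b[1]),
    start_est = unname(b[1] + b[2]),
    end_est = unname(b[1] + b[2] * trials_per_day),
    n_trials_used = nrow(trials),
    n_censored = as.integer(n_censored)
  )
}

#' Daily regressions for every mouse-day of a trial table
#'
#' Vectorised equivalent of applying [fit_daily_regression()] to every
#' mouse-day (closed-form least squares on grouped sums); results agree
#' with the per-day function to numerical precision.
#'
#' @param trials Tidy trial table (see [simulate_cohort()]).
#' @inheritParams fit_daily_regression
#' @return Tibble of daily fits, one row per mouse-day, ordered by
#'   mouse then day.
#' @export
daily_fits <- function(trials, trials_per_day = 7) {
  trials <- trials[!is.na(trials$latency), , drop = FALSE]
  if (any(trials$trial < 1 | trials$trial > trials_per_day)) {
    stop("trial indices must lie within 1..trials_per_day", call. = FALSE)
  }
  key <- paste(trials$mouse, trials$day, sep = "\r")
  if (anyDuplicated(paste(key, trials$trial, sep = "\r"))) {
    stop("duplicate trial indices within one mouse-day", call. = FALSE)
  }
  cens <- if ("censored" %in% names(trials)) {
    as.numeric(trials$censored)
  } else rep(0, nrow(trials))
  x <- trials$trial
  y <- trials$latency
  s <- rowsum(cbind(n = 1, sx = x, sy = y, sxy = x * y, sxx = x * x,
                    nc = cens), key)
  if (any(s[, "n"] < 3)) {
    stop("at least 3 trials are required for a daily regression",
         call. = FALSE)
  }
  n_heavy <- sum(s[, "nc"] >= s[, "n"] / 2)
  if (n_heavy > 0) {
    warning(n_heavy, " mouse-day(s) have at least half their trials ",
            "censored at the ceiling; endpoint estimates are biased low",
            call. = FALSE)
  }
  n <- s[, "n"]
  sxx_c <- s[, "sxx"] - s[, "sx"]^2 / n
  sxy_c <- s[, "sxy"] - s[, "sx"] * s[, "sy"] / n
  slope <- sxy_c / sxx_c
  intercept <- s[, "sy"] / n - slope * s[, "sx"] / n

  first <- which(!duplicated(key))
  meta <- trials[first[match(rownames(s), key[first])], , drop = FALSE]
  fits <- tibble::tibble(
    mouse = meta$mouse,
    group = if ("group" %in% names(meta)) meta$group else NA_character_,
    day = meta$day,
    slope = unname(slope),
    intercept = unname(intercept),
    start_est = unname(intercept + slope),
    end_est = unname(intercept + slope * trials_per_day),
    n_trials_used = as.integer(unname(n)),
    n_censored = as.integer(unname(s[, "nc"]))
  )
  fits[order(fits$mouse, fits$day), ]
}

#' Decompose one mouse's daily fits into learning components
#'
#' From the regression endpoints of consecutive days, derives for each
#' day `d`:
#' * `initial_perf`: estimated skill at trial 1 of day `d`;
#' * `within_day`: estimated gain from trial 1 to trial 7 of day `d`;
#' * `overnight`: change from the end of day `d` to the start of day
#'   `d + 1` (near zero means full retention);
#' * `consolidated`: net day + night gain, start of day `d + 1` minus
#'   start of day `d`.
#'
#' By construction `consolidated = within_day + overnight`. Overnight and
#' consolidated values are defined only across adjacent days actually
#' present; the last day has neither.
#'
#' @param fits Daily fits of a single mouse (rows of [daily_fits()]),
#'   ordered by day, without duplicates.
#' @return Tibble `mouse, group, day, initial_perf, within_day,
#'   overnight, consolidated`.
#' @export
decompose_mouse <- function(fits) {
  if (length(unique(fits$mouse)) > 1) {
    stop("decompose_mouse() expects fits from a single mouse", call. = FALSE)
  }
  if (is.unsorted(fits$day, strictly = TRUE)) {
    stop("daily fits must be strictly ordered by day", call. = FALSE)
  }
  n <- nrow(fits)
  nxt <- match(fits$day + 1L, fits$day)  # NA when the next day is absent
  overnight <- fits$start_est[nxt] - fits$end_est
  consolidated <- fits$start_est[nxt] - fits$start_est
  tibble::tibble(
    mouse = fits$mouse,
    group = if ("group" %in% names(fits)) fits$group else NA_character_,
    day = fits$day,
    initial_perf = fits$start_est,
    within_day = fits$end_est - fits$start_est,
    overnight = overnight,
    consolidated = consolidated
  )
}

#' Learning metrics for every mouse in a fitted table
#'
#' @param fits Output of [daily_fits()] (any number of mice).
#' @return Tibble of per-mouse per-day learning metrics (see
#'   [decompose_mouse()]).
#' @export
learning_metrics <- function(fits) {
  fits <- fits[order(fits$mouse, fits$day), ]
  key <- paste(fits$mouse, fits$day, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (mouse, day) rows in daily fits", call. = FALSE)
  }
  nxt <- match(paste(fits$mouse, fits$day + 1L, sep = "\r"), key)
  tibble::tibble(
    mouse = fits$mouse,
    group = if ("group" %in% names(fits)) fits$group else NA_character_,
    day = fits$day,
    initial_perf = fits$start_est,
    within_day = fits$end_est - fits$start_est,
    overnight = fits$start_est[nxt] - fits$end_est,
    consolidated = fits$start_est[nxt] - fits$start_est
  )
}

#' Per-day phase scatter of learning relationships
#'
#' Assembles the bivariate points compared across groups:
#' * `init_vs_learning`: x = daily initial performance, y = within-day
#'   learning;
#' * `learning_vs_consolidated`: x = within-day learning,
#'   y = consolidated (day + night) learning.
#'
#' The early phase covers training days 1-4; for the consolidated
#' relationship only nights whose both endpoints lie within the phase are
#' used (days 1-3 early, 5-6 late). Each mouse contributes one point per
#' eligible day.
#'
#' @param metrics Output of [learning_metrics()].
#' @param kind `"init_vs_learning"` or `"learning_vs_consolidated"`.
#' @param phase `"early"`, `"late"`, or an integer vector of training
#'   days (for the consolidated relationship, a night `d -> d + 1` is
#'   used only when both `d` and `d + 1` are in the set).
#' @return Tibble `kind, phase, mouse, group, day, x, y`.
#' @export
phase_scatter <- function(metrics,
                          kind = c("init_vs_learning",
                                   "learning_vs_consolidated"),
                          phase = "early") {
  kind <- match.arg(kind)
  if (is.numeric(phase)) {
    days <- as.integer(phase)
    phase_label <- "custom"
  } else {
    phase_label <- match.arg(phase, c("early", "late"))
    days <- if (phase_label == "early") 1:4 else 5:7
  }
  if (kind == "learning_vs_consolidated") {
    # keep nights d -> d+1 whose both endpoints lie in the day set
    days <- days[(days + 1L) %in% days]
  }
  rows <- metrics$day %in% days
  if (kind == "init_vs_learning") {
    x <- metrics$initial_perf
    y <- metrics$within_day
  } else {
    x <- metrics$within_day
    y <- metrics$consolidated
  }
  keep <- rows & !is.na(x) & !is.na(y)
  if (!any(keep)) stop("no points in the requested phase", call. = FALSE)
  tibble::tibble(
    kind = kind, phase = phase_label,
    mouse = metrics$mouse[keep],
    group = if ("group" %in% names(metrics)) metrics$group[keep] else NA_character_,
    day = metrics$day[keep],
    x = x[keep], y = y[keep]
  )
}

#' Rotarod acceleration schedule
#'
#' The rod accelerates linearly from 4 to 40 rpm over 300 s:
#' `speed(t) = 4 + 36 t / 300`. `time_to_speed()` is the exact inverse
#' and gives the time (from acceleration onset) at which a given speed is
#' reached.
#'
#' @param t Time since acceleration onset, seconds, in `[0, 300]`.
#' @return Rod speed in rpm.
#' @examples
#' rotarod_speed(c(0, 300))
#' time_to_speed(20)   # ~133 s, i.e. 130 s to the nearest 10 s
#' @export
rotarod_speed <- function(t) {
  if (any(t < 0 | t > 300)) stop("t must lie within [0, 300] s", call. = FALSE)
  4 + 36 * t / 300
}

#' @rdname rotarod_speed
#' @param v Rod speed in rpm, in `[4, 40]`.
#' @export
time_to_speed <- function(v) {
  if (any(v < 4 | v > 40)) stop("v must lie within [4, 40] rpm", call. = FALSE)
  (v - 4) * 300 / 36
}
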