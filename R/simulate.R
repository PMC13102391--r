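# Per-mouse RNG substreams. Keyed on (base seed, group label, mouse index)
# so adding mice or a second group never perturbs the draws of earlier
# mice, and the two groups receive independent noise.
mouse_stream_seed <- function(seed, group, index) {
  codes <- utf8ToInt(group)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(as.numeric(seed)) * 48271 + h * 131071 + index * 7919) %%
               2147483629)
}

# Truncated-normal draw on [lo, hi] by rejection; degenerate SD clips the
# mean into range.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(clip(mean, lo, hi))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  clip(mean, lo, hi)
}

#' Simulate one mouse's rotarod trajectory
#'
#' Generates the latent skill dynamics and observed latencies of a single
#' mouse. The initial skill is drawn once from a truncated normal; each
#' day `d` the mouse gains `g * lam * (s_max - s_start(d))` latent skill
#' (with `g = learning_scale` on dosed before-task days, else 1), and
#' keeps a fraction `rho` of that gain overnight (`retention_treated` on
#' dosed nights, else `retention_control`). Observed latencies
#' interpolate linearly from `s_start` to `s_end` across the day's
#' trials, plus i.i.d. Gaussian trial noise, minus the execution offset
#' on dosed before-task days, clipped to `[floor, ceiling]`. Trials at
#' the ceiling are flagged censored.
#'
#' @param params A [cohort_params()] object.
#' @param mouse_index Positive integer identifying the mouse within its
#'   group; determines its RNG substream.
#' @param treated Logical: does this mouse belong to the treated group?
#' @param group Group label used in the output (defaults to
#'   `"treated"`/`"control"`).
#' @return List with `trials` (tibble `mouse, group, day, trial,
#'   latency, censored`) and `latent` (tibble `mouse, group, day,
#'   s_start, s_end, gain, rho` where `rho` is the retention applied on
#'   the night after each day, `NA` for the last day).
#' @export
simulate_mouse <- function(params, mouse_index, treated,
                           group = if (treated) "treated" else "control") {
  validate_cohort_params(params)
  core <- simulate_mouse_core(params, mouse_index, treated, group)
  list(trials = tibble::as_tibble(core$trials),
       latent = tibble::as_tibble(core$latent))
}

# Plain-list workhorse shared by simulate_mouse() and simulate_cohort();
# avoids per-mouse tibble construction when assembling large cohorts.
simulate_mouse_core <- function(params, mouse_index, treated, group) {
  stopifnot(mouse_index >= 1)
  p <- params
  nT <- p$trials_per_day
  mouse <- sprintf("%s_%02d", group, mouse_index)

  sub_seed <- mouse_stream_seed(p$seed, group, mouse_index)
  draws <- with_seed(sub_seed, {
    s0 <- rtruncnorm1(p$s0_mean, p$s0_sd, p$floor, p$s_max)
    eps <- matrix(stats::rnorm(p$n_days * nT, 0, p$trial_sd),
                  nrow = p$n_days, ncol = nT, byrow = TRUE)
    list(s0 = s0, eps = eps)
  })

  dosed <- seq_len(p$n_days) %in% p$treatment_days & treated &
    p$treatment_timing != "none"
  g <- ifelse(dosed & p$treatment_timing == "before_task",
              p$learning_scale, 1)
  rho <- ifelse(dosed, p$retention_treated, p$retention_control)
  offset <- ifelse(dosed & p$treatment_timing == "before_task",
                   p$execution_offset, 0)

  s_start <- s_end <- gain <- numeric(p$n_days)
  s_start[1] <- draws$s0
  for (d in seq_len(p$n_days)) {
    gain[d] <- g[d] * p$lam * (p$s_max - s_start[d])
    s_end[d] <- s_start[d] + gain[d]
    if (d < p$n_days) s_start[d + 1] <- s_start[d] + rho[d] * gain[d]
  }

  frac <- (seq_len(nT) - 1) / (nT - 1)
  lat <- outer(s_start, rep(1, nT)) + outer(gain, frac) + draws$eps - offset
  lat <- clip(lat, p$floor, p$ceiling)

  lat_vec <- as.vector(t(lat))
  trials <- list(
    mouse = rep(mouse, p$n_days * nT),
    group = rep(group, p$n_days * nT),
    day = rep(seq_len(p$n_days), each = nT),
    trial = rep(seq_len(nT), times = p$n_days),
    latency = lat_vec,
    censored = lat_vec >= p$ceiling
  )
  latent <- list(
    mouse = rep(mouse, p$n_days), group = rep(group, p$n_days),
    day = seq_len(p$n_days),
    s_start = s_start, s_end = s_end, gain = gain,
    rho = c(rho[-p$n_days], NA_real_)
  )
  list(trials = trials, latent = latent)
}

#' Simulate a two-group rotarod cohort
#'
#' Simulates `n_mice_per_group` control mice (all treatment knobs
#' inactive) and the same number of treated mice under the treatment
#' effects encoded in `params`. Each mouse has its own deterministic RNG
#' substream derived from the cohort seed, so re-running with the same
#' parameters reproduces the table bit-for-bit and enlarging the cohort
#' leaves earlier mice unchanged.
#'
#' @param params A [cohort_params()] object.
#' @return List of two tibbles: `trials` (one row per trial, columns
#'   `mouse, group, day, trial, latency, censored`) and `latent` (ground
#'   truth skill per mouse-day, for parameter-recovery checks).
#' @examples
#' sim <- simulate_cohort(default_scenarios(n_mice_per_group = 3)$control)
#' head(sim$trials)
#' @export
simulate_cohort <- function(params) {
  validate_cohort_params(params)
  sims <- c(
    lapply(seq_len(params$n_mice_per_group), function(i)
      simulate_mouse_core(params, i, treated = FALSE, group = "control")),
    lapply(seq_len(params$n_mice_per_group), function(i)
      simulate_mouse_core(params, i, treated = TRUE, group = "treated"))
  )
  cat_field <- function(part) {
    tibble::as_tibble(lapply(
      stats::setNames(nm = names(sims[[1]][[part]])),
      function(col) do.call(c, lapply(sims, function(s) s[[part]][[col]]))
    ))
  }
  list(trials = cat_field("trials"), latent = cat_field("latent"))
}

#' Read a tidy rotarod trial table
#'
#' Reads and validates a CSV with columns `mouse, group, day, trial,
#' latency` (and optionally `censored`; when absent, no trial is marked
#' censored unless `ceiling` is supplied).
#'
#' @param path CSV file path.
#' @param ceiling Optional censoring latency in seconds used to derive
#'   the `censored` flag when the file lacks that column.
#' @return Tibble with the trial-table schema of [simulate_cohort()].
#' @export
read_trials <- function(path, ceiling = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse", "group", "day", "trial", "latency")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"censored" %in% names(df)) {
    df$censored <- if (is.null(ceiling)) FALSE else df$latency >= ceiling
  }
  df$censored <- as.logical(df$censored)
  if (anyNA(df$latency)) stop("latency column contains NA", call. = FALSE)
  if (any(duplicated(df[c("mouse", "day", "trial")]))) {
    stop("duplicate (mouse, day, trial) rows", call. = FALSE)
  }
  tibble::as_tibble(df[c("mouse", "group", "day", "trial", "latency",
                         "censored")])
}
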