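#' Parameterise a synthetic rotarod cohort
#'
#' Bundles and validates the latent-skill dynamics, noise, censoring and
#' treatment-effect parameters of the synthetic cohort generator (see
#' [simulate_cohort()]). The latent skill of each mouse lives on the
#' latency-to-fall scale (seconds) and relaxes towards an asymptote
#' `s_max` with per-day gain fraction `lam`; overnight, a fraction
#' `retention_control` (or `retention_treated` on dosed days) of the
#' day's gain is retained.
#'
#' Treatment knobs model three distinct deficits:
#' * `learning_scale` < 1: multiplicative online-learning deficit, active
#'   only when the drug is on board during training
#'   (`treatment_timing == "before_task"`).
#' * `retention_treated` < `retention_control`: offline-consolidation
#'   deficit, active on the nights following dosed days.
#' * `execution_offset` > 0: additive latency reduction while the drug is
#'   active during the task (`"before_task"` only), leaving the latent
#'   skill untouched.
#'
#' @param n_mice_per_group Mice per group (control and treated).
#' @param n_days Training days (default 7).
#' @param trials_per_day Trials per day (default 7).
#' @param s0_mean,s0_sd Mean and SD of the day-1 initial latent skill,
#'   seconds; the draw is truncated to `[floor, s_max]`.
#' @param s_max Asymptotic latent skill, seconds; must not exceed
#'   `ceiling`.
#' @param lam Per-day learning gain fraction in (0, 1]: the daily gain is
#'   `lam * (s_max - s_start)`.
#' @param retention_control Overnight retention fraction in `[0, 1]` for
#'   untreated nights (default 1: full consolidation).
#' @param trial_sd Trial-to-trial noise SD, seconds.
#' @param ceiling Censoring latency, seconds (default 300; trials at the
#'   ceiling are recorded as the ceiling and flagged censored).
#' @param floor Minimum recordable latency, seconds.
#' @param learning_scale Online-learning deficit multiplier in `[0, 1]`.
#' @param retention_treated Overnight retention under offline disruption,
#'   in `[0, 1]`.
#' @param execution_offset Additive latency reduction while dosed,
#'   seconds.
#' @param treatment_days Integer day indices on which the treated group
#'   is dosed.
#' @param treatment_timing One of `"none"`, `"before_task"`,
#'   `"after_task"`. Before-task dosing affects same-day trials (learning
#'   and execution) and the following night; after-task dosing affects
#'   only the following night.
#' @param seed Integer RNG seed; identical parameters and seed give a
#'   bit-identical cohort.
#' @return A validated `cohort_params` list.
#' @seealso [default_scenarios()], [simulate_cohort()]
#' @export
cohort_params <- function(n_mice_per_group = 10,
                          n_days = 7,
                          trials_per_day = 7,
                          s0_mean = 60,
                          s0_sd = 15,
                          s_max = 260,
                          lam = 0.35,
                          retention_control = 1,
                          trial_sd = 25,
                          ceiling = 300,
                          floor = 5,
                          learning_scale = 1,
                          retention_treated = 1,
                          execution_offset = 0,
                          treatment_days = seq_len(n_days),
                          treatment_timing = c("none", "before_task", "after_task"),
                          seed = 1L) {
  treatment_timing <- match.arg(treatment_timing)
  p <- list(
    n_mice_per_group = as.integer(n_mice_per_group),
    n_days = as.integer(n_days),
    trials_per_day = as.integer(trials_per_day),
    s0_mean = s0_mean, s0_sd = s0_sd, s_max = s_max, lam = lam,
    retention_control = retention_control,
    trial_sd = trial_sd, ceiling = ceiling, floor = floor,
    learning_scale = learning_scale,
    retention_treated = retention_treated,
    execution_offset = execution_offset,
    treatment_days = as.integer(sort(unique(treatment_days))),
    treatment_timing = treatment_timing,
    seed = as.integer(seed)
  )
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  stopifnot_param <- function(ok, msg) {
    if (!isTRUE(ok)) stop("invalid cohort parameters: ", msg, call. = FALSE)
  }
  stopifnot_param(p$n_mice_per_group >= 1L, "n_mice_per_group must be >= 1")
  stopifnot_param(p$n_days >= 1L, "n_days must be >= 1")
  stopifnot_param(p$trials_per_day >= 2L, "trials_per_day must be >= 2")
  stopifnot_param(p$floor < p$s0_mean && p$s0_mean < p$s_max,
                  "floor < s0_mean < s_max is required")
  stopifnot_param(p$s_max <= p$ceiling, "s_max must be <= ceiling")
  stopifnot_param(p$lam > 0 && p$lam <= 1, "lam must lie in (0, 1]")
  stopifnot_param(p$retention_control >= 0 && p$retention_control <= 1,
                  "retention_control must lie in [0, 1]")
  stopifnot_param(p$retention_treated >= 0 && p$retention_treated <= 1,
                  "retention_treated must lie in [0, 1]")
  stopifnot_param(p$learning_scale >= 0 && p$learning_scale <= 1,
                  "learning_scale must lie in [0, 1]")
  stopifnot_param(p$trial_sd >= 0, "trial_sd must be >= 0")
  stopifnot_param(p$s0_sd >= 0, "s0_sd must be >= 0")
  stopifnot_param(p$execution_offset >= 0, "execution_offset must be >= 0")
  stopifnot_param(all(p$treatment_days >= 1L & p$treatment_days <= p$n_days),
                  "treatment_days must lie within 1..n_days")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic rotarod cohort parameters\n")
  cat(sprintf("  %d mice/group, %d days x %d trials, seed %d\n",
              x$n_mice_per_group, x$n_days, x$trials_per_day, x$seed))
  cat(sprintf("  skill: s0 ~ N(%.1f, %.1f) in [%.0f, %.0f], lam = %.2f, s_max = %.0f\n",
              x$s0_mean, x$s0_sd, x$floor, x$s_max, x$lam, x$s_max))
  cat(sprintf("  noise sd %.1f s, ceiling %.0f s, retention (ctrl) %.2f\n",
              x$trial_sd, x$ceiling, x$retention_control))
  cat(sprintf("  treatment: timing %s, days {%s}, learning_scale %.2f, retention %.2f, offset %.0f s\n",
              x$treatment_timing, paste(x$treatment_days, collapse = ","),
              x$learning_scale, x$retention_treated, x$execution_offset))
  invisible(x)
}

#' Named cohort presets mirroring the chemogenetic intervention designs
#'
#' Returns five `cohort_params` presets sharing the same baseline skill
#' dynamics and differing only in their treatment knobs:
#'
#' * `control`: neutral treated group (no deficit of any kind).
#' * `online_learning_deficit`: drug on board during training every day
#'   halves the daily learning gain (`learning_scale = 0.5`).
#' * `offline_consolidation_deficit`: dosing after the sessions of days
#'   1-3 reduces overnight retention to 0.3 on those nights.
#' * `execution_deficit`: dosing before the task subtracts 40 s from
#'   observed latencies without touching the latent skill.
#' * `combined`: online learning and consolidation deficits together.
#'
#' @param n_mice_per_group Mice per group for every preset.
#' @param seed Base RNG seed shared by the presets.
#' @return Named list of `cohort_params`.
#' @export
default_scenarios <- function(n_mice_per_group = 10, seed = 1L) {
  list(
    control = cohort_params(
      n_mice_per_group = n_mice_per_group, seed = seed,
      treatment_days = 1:3, treatment_timing = "none"),
    online_learning_deficit = cohort_params(
      n_mice_per_group = n_mice_per_group, seed = seed,
      learning_scale = 0.5, treatment_days = 1:7,
      treatment_timing = "before_task"),
    offline_consolidation_deficit = cohort_params(
      n_mice_per_group = n_mice_per_group, seed = seed,
      retention_treated = 0.3, treatment_days = 1:3,
      treatment_timing = "after_task"),
    execution_deficit = cohort_params(
      n_mice_per_group = n_mice_per_group, seed = seed,
      execution_offset = 40, treatment_days = 1:7,
      treatment_timing = "before_task"),
    combined = cohort_params(
      n_mice_per_group = n_mice_per_group, seed = seed,
      learning_scale = 0.5, retention_treated = 0.3,
      treatment_days = 1:7, treatment_timing = "before_task")
  )
}
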