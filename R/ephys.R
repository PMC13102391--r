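#' Spike-train quality metrics
#'
#' Computes, from a sorted spike-time vector, the quantities used to
#' filter single units after spike sorting: mean firing rate, fraction of
#' inter-spike intervals violating a refractory period, and presence
#' ratio (fraction of equal-width time bins containing at least one
#' spike, guarding against prolonged silent stretches). Signal-to-noise
#' ratio and amplitude cutoff require waveform data and are accepted as
#' externally supplied numbers.
#'
#' @param times Numeric vector of spike times in seconds, non-decreasing,
#'   within `[0, duration]`.
#' @param duration Recording duration in seconds (> 0).
#' @param refractory Refractory period in seconds used for the ISI
#'   violation count (default 2 ms).
#' @param n_presence_bins Number of equal-width bins for the presence
#'   ratio (default 60).
#' @param snr,amplitude_cutoff Externally computed waveform metrics
#'   (default `NA`).
#' @return One-row tibble: `snr, isi_violation_fraction,
#'   amplitude_cutoff, presence_ratio, firing_rate, n_spikes`.
#' @export
unit_metrics <- function(times, duration, refractory = 0.002,
                         n_presence_bins = 60, snr = NA_real_,
                         amplitude_cutoff = NA_real_) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (length(times)) {
    if (is.unsorted(times)) stop("spike times must be sorted", call. = FALSE)
    if (any(times < 0 | times > duration)) {
      stop("spike times must lie within [0, duration]", call. = FALSE)
    }
  }
  n <- length(times)
  isi_frac <- if (n >= 2) {
    isi <- diff(times)
    sum(isi < refractory) / length(isi)
  } else 0
  presence <- if (n >= 1) {
    bin <- pmin(floor(times / duration * n_presence_bins) + 1L,
                n_presence_bins)
    length(unique(bin)) / n_presence_bins
  } else 0
  tibble::tibble(
    snr = snr,
    isi_violation_fraction = isi_frac,
    amplitude_cutoff = amplitude_cutoff,
    presence_ratio = presence,
    firing_rate = n / duration,
    n_spikes = n
  )
}

#' Single-unit quality filter
#'
#' A unit passes when SNR > 5, ISI violation fraction < 1%, amplitude
#' cutoff < 0.1, presence ratio > 0.9, firing rate > 0.1 Hz, and at
#' least 50 spikes were detected. All inequalities are strict except the
#' spike count. A metric that is `NA` cannot certify its criterion and
#' fails it.
#'
#' @param metrics One-row data frame or named list with fields `snr`,
#'   `isi_violation_fraction`, `amplitude_cutoff`, `presence_ratio`,
#'   `firing_rate`, `n_spikes` (see [unit_metrics()]).
#' @param snr_min,isi_max,amplitude_max,presence_min,rate_min,n_min
#'   Filter thresholds.
#' @return List with `pass` (logical) and `failed` (character vector of
#'   failed criteria, empty when passing).
#' @export
quality_filter <- function(metrics, snr_min = 5, isi_max = 0.01,
                           amplitude_max = 0.1, presence_min = 0.9,
                           rate_min = 0.1, n_min = 50) {
  ok <- function(x) !is.na(x) && isTRUE(x)
  checks <- c(
    snr = ok(metrics$snr > snr_min),
    isi_violation_fraction = ok(metrics$isi_violation_fraction < isi_max),
    amplitude_cutoff = ok(metrics$amplitude_cutoff < amplitude_max),
    presence_ratio = ok(metrics$presence_ratio > presence_min),
    firing_rate = ok(metrics$firing_rate > rate_min),
    n_spikes = ok(metrics$n_spikes >= n_min)
  )
  list(pass = all(checks), failed = names(checks)[!checks])
}

#' Firing-rate modulation index
#'
#' Normalised change in firing rate after versus before an injection,
#' expressed as a percentage:
#' `100 * (rate_post - rate_pre) / (rate_post + rate_pre)`. It is bounded
#' between -100% (total suppression) and +100% (discharge only
#' post-treatment), and is antisymmetric under swapping pre and post.
#'
#' @param rate_pre,rate_post Non-negative firing rates in Hz (not both
#'   zero; vectors are recycled element-wise).
#' @return Modulation in percent, in `[-100, 100]`.
#' @examples
#' modulation_index(0, 5)    # +100: discharge only post-treatment
#' modulation_index(5, 0)    # -100: total suppression
#' modulation_index(10, 6.5)
#' @export
modulation_index <- function(rate_pre, rate_post) {
  if (any(rate_pre < 0) || any(rate_post < 0)) {
    stop("firing rates must be non-negative", call. = FALSE)
  }
  if (any(rate_pre + rate_post == 0)) {
    stop("modulation is undefined when both rates are zero", call. = FALSE)
  }
  100 * (rate_post - rate_pre) / (rate_post + rate_pre)
}

#' Simulate a homogeneous Poisson spike train
#'
#' Test fixture for the quality metrics: draws a Poisson spike count for
#' the requested duration and places the spikes uniformly (the
#' order-statistics construction of a homogeneous Poisson process).
#'
#' @param rate Firing rate in Hz (>= 0).
#' @param duration Recording duration in seconds (> 0).
#' @param seed RNG seed.
#' @return List with `times` (sorted spike times) and `duration`.
#' @export
simulate_poisson_unit <- function(rate, duration, seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  times <- with_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    sort(stats::runif(n, 0, duration))
  })
  list(times = times, duration = duration)
}
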