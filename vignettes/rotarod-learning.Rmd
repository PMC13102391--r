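---
title: "Decomposing rotarod learning and offline consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing rotarod learning and offline consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotalearn)
```

## The problem

On the accelerating rotarod (4 to 40 rpm over 300 s; `rotarod_speed()`
and `time_to_speed()` encode this ramp), mice trained seven trials a
day for seven days improve rapidly over the first four days (the early
phase) and plateau over the last three. Two processes drive the curve:
online learning within each session, and offline consolidation of that
learning during the rest period between sessions. A treatment — for
instance transient chemogenetic inhibition of cerebellar output
neurons, during or after the sessions — can selectively impair either
process, or merely degrade execution. This package implements the
statistical decomposition that tells these apart, and a simulator for
validating it.

## Daily regression and the learning decomposition

Single-trial latencies fluctuate strongly, so each mouse-day is
summarised by an ordinary least-squares line of latency on trial index
(1–7). The fitted values at trials 1 and 7 (`start_est`, `end_est`)
estimate the day's initial and final skill even when intermediate
trials are missing; the regression endpoints are provably less noisy
than the raw first-trial latency (a property the test suite checks on
simulated cohorts). From consecutive days the package derives
within-day learning, overnight change, and consolidated learning, with
the identity `consolidated = within_day + overnight` holding by
construction.

Numerical and degenerate-input choices:

* Censored trials (recorded at the 300-s ceiling) enter the regression
  as recorded — transforming them would require a censoring model the
  latency data cannot identify — and a warning is raised when at least
  half a day's trials are censored, since endpoints are then biased
  low.
* At least 3 trials are required per day; duplicate trial indices are
  an error, not silently averaged.
* Day gaps are allowed; overnight/consolidated quantities are defined
  only across adjacent days actually present.
* `daily_fits()` computes the same least squares in closed form over
  grouped sums for speed; a test pins it to the per-day `lm()` path.

The early phase is days 1–4 and the late phase days 5–7. For the
learning × consolidated scatter only nights with both endpoints inside
the phase are used (nights 1→2, 2→3, 3→4 early). Whether the night into
day 5 should count as "early" is genuinely open; excluding it keeps the
two scatters on the same training days and is the convention here.

## Group comparison about the control Deming line

Daily learning is strongly negatively related to the day's initial
performance (less headroom near the ceiling), so group differences in
learning must be assessed conditional on initial performance, and
differences in consolidation conditional on the amount learned. Both
coordinates of those scatters are derived from the same latency
measurements, so their errors are comparable in scale and an ordinary
regression of y on x would be attenuated. The package therefore fits an
equal-variance (δ = 1) Deming — i.e. orthogonal — regression to the
*control* scatter and compares groups through their signed
perpendicular residuals about that line with a two-sided Wilcoxon
rank-sum test.

Design choices, made where the procedure was underdetermined:

* δ is fixed at 1 and only exposed for testing; no δ-estimation or
  attenuation correction is attempted.
* Bootstrap CIs resample (x, y) points i.i.d. with replacement,
  B = 1000 by default, percentile 95% intervals, seeded. Resamples with
  degenerate covariance are dropped from the percentile computation.
* The rank test is unpaired (groups are different animals), exact when
  both groups have ≤ 12 tie-free residuals, otherwise the tie-corrected
  normal approximation.
* Each (mouse, day) point is treated as independent, as the scatter
  itself does. Days within a mouse are in fact correlated; the p-values
  are therefore anti-conservative in the presence of strong per-mouse
  idiosyncrasies. A mixed-model alternative is deliberately out of
  scope; treat borderline p-values with caution.
* A vertical point cloud (zero x–y covariance with all variance in y)
  raises an error rather than returning an infinite slope.

Scatters can be summarised by `ellipse_summary()`: the
maximum-likelihood bivariate normal's contour at squared Mahalanobis
radius `qchisq(mass, 2)`, enclosing 50% of the fitted mass by default
(verified by Monte Carlo in the tests).

## The synthetic cohort generator

No quantitative model of rotarod learning is established in the
literature; the generator's saturating-gain recursion is an explicit
artifact choice, selected as the simplest dynamics that reproduce the
qualitative features the analysis relies on: saturating multi-day
curves, learning concentrated in the early phase, and the inverse
relation between initial performance and daily gain. Latent skill
lives on the latency scale (seconds):

* `s_start(1) ~ N(s0_mean, s0_sd)` truncated to `[floor, s_max]`;
* daily gain `g · λ · (s_max − s_start)` with `g = learning_scale` on
  dosed before-task days, else 1;
* overnight `s_start(d+1) = s_start(d) + ρ_d · gain(d)` with
  `ρ_d = retention_treated` on dosed nights, else `retention_control`;
* observed latencies interpolate linearly across trials (matching the
  analysis's own linear daily fits), plus `N(0, trial_sd²)` noise,
  minus `execution_offset` on dosed before-task days (the drug acts
  within the hour and lasts several hours, so after-task dosing cannot
  affect same-day trials), clipped to `[floor, ceiling]` after noise,
  with ceiling trials flagged censored.

Default study conditions, chosen once: `s0_mean = 60`, `s0_sd = 15`,
`s_max = 260`, `λ = 0.35` per day (day-1 start near one minute,
plateau around 250 s by days 5–7), `trial_sd = 25` s (between-trial
scatter of the same order as daily learning), 10 mice/group,
7 days × 7 trials, ceiling 300 s, floor 5 s. The deficit presets use
`learning_scale = 0.5`, `retention_treated = 0.3` (after-task dosing on
days 1–3, as in the behavioural design they emulate) and
`execution_offset = 40` s.

Per-mouse RNG substreams are derived deterministically from the cohort
seed, the group label and the mouse index, so cohorts are bit-for-bit
reproducible, enlarging a cohort leaves earlier mice untouched, and the
two groups receive independent noise — which keeps control-vs-control
comparisons a genuine null (the tests verify ~nominal false-positive
calibration over 100 seeds).

What the generator does *not* emulate: per-mouse learning-rate
heterogeneity beyond the initial skill, fatigue or within-day
nonlinearity, gait strategy switches, censoring-informative skill, or
any pharmacokinetics beyond the on/off dosing flags. Passing
parameter-recovery tests therefore show that the pipeline detects the
deficits it parameterises at realistic noise — not that real cohorts
satisfy the model.

## Companion measurement modules

*Ephys QC.* `unit_metrics()` computes firing rate, ISI-violation
fraction (2-ms refractory default; not specified by convention, so
configurable) and presence ratio (60 equal bins by default);
`quality_filter()` applies the strict thresholds SNR > 5, ISI < 1%,
amplitude cutoff < 0.1, presence > 0.9, rate > 0.1 Hz, n ≥ 50. SNR and
amplitude cutoff require waveforms the package does not model and are
accepted as supplied numbers. `modulation_index()` is the normalised
difference `100 (post − pre)/(post + pre)`: the verbal
"difference divided by the average" form would span ±200%, which
contradicts the ±100% bounds that give the index its meaning (−100 =
total suppression, +100 = discharge only post-treatment); the bounded
normalised-difference form is implemented and is antisymmetric in its
arguments.

*Gait.* `compute_gait()` computes stride length, hindbase width,
linearity, sigma, gait width and the alternation coefficient from
centroid footprint coordinates; the travel direction defaults to the
first principal axis of the right prints. Foot opening angle needs a
toe landmark absent from a centroid representation and is out of
scope. Left–right pairing takes the left print enclosed by each
consecutive right-print pair. All metrics are rigid-motion invariant;
the length-valued ones scale with the coordinates.

*Tracking.* `detect_centroid()` uses median denoising
(edge-preserving), Gaussian blur (σ = 1 px default), an automatic Otsu
threshold (manual override available), connected-component labelling
with a minimum-area gate (cable and dirt artifacts are small and
high-spatial-frequency; the gate plus blur removes them) and the area
centroid of the largest component. Blank or near-contrastless frames
yield a no-detection flag. `track_and_smooth()` fits per-coordinate
cubic smoothing splines under the smoothing condition
`RSS ≤ 0.2 × N` (N valid frames), bridging detection gaps shorter than
0.5 s and splitting the trajectory at longer ones. `kinematics()` sums
frame-to-frame displacements for total distance and averages
instantaneous speed over centred 1-s windows (centred rather than
trailing — an arbitrary but documented choice).

## Scenario recovery and problem sizes

`run_full_analysis()` chains simulate → decompose → early-phase
scatters → control Deming fits → residual comparisons → JSON/CSV
report. Across seeded replicates, the offline-consolidation scenario is
flagged only by the learning × consolidated comparison and the
online-learning scenario only by the initial × learning comparison,
while control-vs-control stays at the nominal false-positive rate; the
test suite runs each of these over 100 seeds at the default 10
mice/group, and the imaging tests use 60–100 frames of 200×200 px —
sizes chosen so the whole suite completes in a few minutes while
keeping the Monte Carlo margins comfortable.

## Known limitations

* Pseudo-replication across days within mouse (see above).
* Censoring is handled by flag-and-warn, not modelled; cohorts
  training close to the ceiling need a tobit-style extension.
* The Deming bootstrap is the simple pairs bootstrap; no BCa
  correction.
* The simulator's linear within-day interpolation makes the daily OLS
  exactly correct under the model — convenient for validation, but it
  means recovery tests cannot detect misfit of the linear daily model
  itself.
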