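Package: rotalearn
Title: Learning-Curve Decomposition and Offline-Consolidation Statistics
    for Accelerating-Rotarod Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing motor-skill learning on the accelerating
    rotarod. Per-animal daily learning curves are reduced by linear
    regression to estimated trial-1 and trial-7 skill levels, from which
    within-day learning, overnight change and consolidated (day + night)
    learning are derived. Group effects on the learning/consolidation
    relationships are assessed with equal-variance Deming (orthogonal)
    regression, bootstrap confidence intervals, and Wilcoxon rank tests on
    signed orthogonal residuals relative to the control regression line.
    Includes a seeded synthetic-cohort generator with latent skill dynamics
    (online learning, overnight retention and execution deficits) for
    power analysis and pipeline validation, plus companion utilities for
    spike-train quality control and firing-rate modulation indices,
    footprint gait morphometry, and open-field centroid video tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    dplyr,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
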