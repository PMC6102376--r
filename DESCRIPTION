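Package: reachprior
Title: Simulation and Analysis of Prior Learning in Visuomotor Reaching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates and analyses a stochastic visuomotor reaching task in
    which a lateral cursor shift is drawn on every trial from a Gaussian
    prior and brief midpoint feedback of varying reliability is the only
    evidence about it.  Provides trial schedulers with exact per-block
    condition ratios, three candidate observer models (full compensation,
    minimal mapping, Bayesian reliability-weighted estimation) with
    extrinsic or intrinsic coding of the perturbation, a minimum-jerk
    synthetic trajectory generator sampled at 200 Hz, movement-offset
    detection by a combined velocity and reach-extent criterion,
    cursor-error slope fits, interlimb-generalization measures with
    moving-window summaries, and repeated-measures statistics (Welch,
    Student and paired t tests; one-way repeated-measures ANOVA with the
    Mauchly sphericity test and Greenhouse-Geisser correction) implemented
    from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
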