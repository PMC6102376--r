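---
title: "Simulating prior learning and interlimb generalization in reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prior learning and interlimb generalization in reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachprior)
```

## The task and the question

A subject makes 20 cm reaches from a start target to an end target while the
visual cursor representing the hand is displaced laterally on every trial by
an amount drawn from a Gaussian prior (mean 1 cm rightward, SD 0.5 cm). The
only evidence about the current trial's shift is a brief (100 ms) flash of
feedback at the movement midpoint whose reliability is manipulated across
four conditions scheduled 3:1:1:1 within every 1080-trial block (540 clear
single-sphere trials, 180 moderate clouds with SD 1 cm, 180 large clouds
with SD 2 cm, 180 trials with no midpoint feedback at all). Endpoint cursor
feedback is given only in the clear condition. Hand position is sampled at
200 Hz, and a reach that fails to cross the lower bound of the end target
within 4000 ms times out.

Two questions drive the analyses. First, do subjects *learn the prior* and
combine it with the current evidence in proportion to reliability, as a
Bayesian estimator would, rather than fully compensating for whatever they
saw, or applying one fixed learned correction? Second, when a prior learned
with the right hand is probed with the untrained left hand, is the learned
mapping expressed in extrinsic (screen-based) or intrinsic (joint-based)
coordinates?

This package simulates the full paradigm with synthetic observers so every
analysis in the pipeline can be exercised and validated with no human data.

## Observer models

All three candidate strategies aim the reach so as to cancel an estimate of
the imposed shift $x_{true}$:

* **Full compensation** cancels the sensed shift $x_{sensed}$ exactly.
  Noisier feedback inflates endpoint variance but the mean cursor error
  stays at zero for every condition (zero error-vs-shift slope).
* **Minimal mapping** applies one learned constant -- the running estimate
  of the prior mean -- on every trial, regardless of the feedback. The
  cursor error then tracks the shift one-for-one (unit slope) and crosses
  zero at the prior mean.
* **Bayesian estimation** combines prior and evidence weighted by their
  relative variances,
  $$\mu_{est} = \frac{\sigma_s^2}{\sigma_s^2+\sigma_p^2}\,\mu_{prior}
             + \frac{\sigma_p^2}{\sigma_s^2+\sigma_p^2}\,x_{sensed},
  \qquad
  \sigma_{sp}^2 = \frac{\sigma_s^2\sigma_p^2}{\sigma_s^2+\sigma_p^2},$$
  so the expected cursor error is
  $\frac{\sigma_s^2}{\sigma_s^2+\sigma_p^2}(x_{true}-\mu_{prior})$: a slope
  between 0 and 1 that grows with sensory noise, always crossing the
  abscissa at the prior mean. With no feedback the likelihood is flat and
  the estimate collapses onto the learned prior mean -- which is why the
  no-feedback trials are the clean readout of the prior used throughout the
  analyses.

```{r}
predicted_error_slope(c(0.1, 1, 2, NA), sigma_p_cm = 0.5)
```

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| prior mean / SD | 1 cm / 0.5 cm | the task's true shift distribution |
| $\sigma_s$ per condition | 0.1 / 1 / 2 cm, absent | the cloud SDs used as effective sensory SDs; the task manipulates but never calibrates them, so they are configurable |
| $\sigma_p$ (observer) | 0.5 cm | a converged observer knows the true prior spread |
| motor noise | 0.3 cm | lateral execution noise on the endpoint; typical trial-to-trial reach scatter at this amplitude |
| movement duration | 800 ms | a comfortable 20 cm reach, well inside the 4000 ms limit |
| spheres per cloud | 50 | cloud geometry (configurable; parts of the original report suggest 25 for the moderate cloud, so the count is exposed rather than hard-coded) |

The **converged** observer (the default) starts with its prior-mean
estimate at the true prior mean and learning disabled; that is the regime
all steady-state predictions refer to. Acquisition can be simulated with a
Kalman-style running estimate: each sensed shift updates the mean with gain
$u^2/(u^2+\sigma_s^2)$, so the estimate's uncertainty $u$ shrinks
monotonically. The steady state -- convergence on the true prior mean -- is
the only property downstream analyses rely on; the update rule itself is a
modelling convenience, not a claim about human learning dynamics. The
minimal-mapping observer learns only from the clear condition, because
endpoint error feedback -- the only signal that strategy can exploit -- is
provided there alone.

## Synthetic kinematics

Trajectories are generated, not recorded: the longitudinal profile is
minimum-jerk (peak speed $1.875\,L/T$ at mid-reach), and the lateral profile
ramps to a first-half aim (taken from the prior estimate alone) until the
midpoint, then re-aims smoothly to the planned compensation plus motor
noise. This is the simplest kinematic family that honours the structure of
the task -- evidence arrives at the midpoint, so the plan can only change
then -- and that exercises the movement-offset criterion nontrivially.

Endpoints are *always* recovered through the kinematics module, never
copied from the generator: movement offset is the first sample whose speed
drops below 5% of peak *after* 19 cm of the reach have been covered (the
spatial clause keeps the slow samples near the start target from ever being
selected), and the endpoint is the position at that sample. Speeds come
from central finite differences (one-sided at the ends), unsmoothed by
default since the original processing is unspecified; a moving-average
window is available. One consequence worth knowing: the offset sample sits
in the deceleration tail a few samples before the very end, so recovered
endpoints differ from the generator's nominal endpoint by about 1% of the
within-trial correction -- visible as a ~1% shrinkage of fitted slopes,
well inside every tolerance used here.

What the generator does *not* emulate: biomechanics (no joint dynamics, no
speed-accuracy trade-offs), feedback-delay dynamics inside a movement,
online corrections beyond the single midpoint re-aim, fatigue or attention
drift, and any explicit/implicit decomposition of learning. Passing tests
therefore validate the *pipeline* -- schedulers, models, offset detection,
measures, statistics -- on data with known ground truth; they are not
evidence about real subjects.

## Sign conventions for generalization

Percent interlimb generalization is the ratio of mean early left-hand
no-feedback endpoints (trials 1080--1180) to mean late right-hand endpoints
(trials 980--1080), times 100. Ranges are 1-based and inclusive (101
trials each, matching the conventional overlapping notation; trial 1080 --
the last right-hand trial -- falls in both windows, which changes group
means by under 1%).

`percent_generalization()` reports the raw ratio. For a
congruent-intrinsic (CI) session, where the testing-phase shifts are
mirrored on screen, `interlimb_generalization()` first expresses the early
left-hand mean relative to the *testing-phase* perturbation direction
(a sign flip). Under that convention the signed percentage is positive when
transfer is appropriate to the testing limb's perturbation and negative
when the endpoint lands on the wrong side: a converged extrinsically coded
observer scores about +100% in CE and about -100% in CI, the directional
asymmetry expected if learning lives in screen coordinates. The raw ratio
is always retained as `raw_signed_percent`. Group summaries report both the
ratio of group means and the mean of per-subject ratios, which differ
slightly whenever subjects differ; neither is privileged.

```{r, eval = FALSE}
subjects <- lapply(1:7, function(i) {
  generate_subject(make_design("CE", seed = i),
                   observer_params("BAYES"), seed = 100 + i)
})
group_generalization(subjects)
```

## Numerical and design choices

* **Block-exact scheduling.** Conditions are shuffled within each
  1080-trial block with exact 540/180/180/180 counts (an i.i.d. mode
  exists); shifts are never truncated, so ~2.3% of trials shift leftward.
* **Seeding.** Every stochastic entry point takes a `seed` and restores the
  caller's RNG state; equal seeds reproduce sessions exactly, and the CE/CI
  designs consume identical draws so their left-hand shifts mirror trial by
  trial.
* **Slope fits.** Ordinary least squares on trial-level points; the
  conventional 11 equal-count bins of imposed shift are computed for
  display only, since binning adds nothing to the estimate. Conditions with
  fewer than two distinct shifts are flagged degenerate rather than fitted.
* **Offset threshold.** Strictly below 5% of peak, matching the stated
  inequality; ties on the grid resolve to the earliest qualifying sample.
* **Repeated-measures ANOVA.** Sums of squares from the two-way
  decomposition; Mauchly's W from the covariance of orthonormalized level
  contrasts with Box's chi-square approximation (including the second-order
  term, coefficient-for-coefficient as in `stats::mauchly.test`);
  Greenhouse--Geisser $\hat\varepsilon$ from the same contrast covariance.
  The correction is applied only when Mauchly rejects at .05 (an
  always/never switch exists). With two levels the F statistic equals the
  squared paired t, which the tests verify numerically.
* **Degenerate inputs.** Identical samples give t = 0, p = 1 rather than
  0/0; empty endpoint selections are explicit errors; timeouts propagate as
  missing endpoints and are excluded from every selection.

## Problem sizes

The validation suite simulates single subjects of 300--5000 trials for
model set points and 7-subject groups of full 2160-trial sessions for
slope recovery and the CE/CI asymmetry -- the group size the paradigm
itself uses, which brings the slope standard error per condition to ~0.015
and the group generalization standard error to ~4 percentage points.
Statistical calibration uses 5000 null replicates per test. The whole
suite runs in well under a minute on one core.

## Known limitations

* The trajectory family is one of many consistent with the task; offsets
  and endpoints are robust to it, but time-resolved measures (e.g. reaction
  or correction latencies) are not modelled at all.
* The learning rule is deliberately minimal; it converges to the right
  mean but its trial constant should not be compared to human acquisition
  curves.
* Percent generalization is undefined when late right-hand endpoints
  average zero, and unstable when they are near zero; the functions refuse
  the former and leave the latter to the caller's judgment.
* The Mauchly p value is an asymptotic approximation; at very small n it
  inherits the usual liberal/conservative wobble of that expansion.
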