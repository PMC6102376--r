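# reachprior

Simulation and analysis of **prior learning in visuomotor reaching**: does a
person reaching under a stochastic lateral cursor shift learn the shift's
distribution and combine it with uncertain visual feedback the way a
Bayesian estimator would — and when the prior is learned with one arm, does
it transfer to the other in screen (extrinsic) or joint (intrinsic)
coordinates?

The package is aimed at sensorimotor-learning researchers who want a fully
synthetic, ground-truth-known version of this paradigm: every stage — trial
scheduling, observer behaviour, reach kinematics, endpoint extraction,
behavioural measures, inferential statistics — is simulated and analysable
with no human data.

## The task and the models

Each trial is a 20 cm reach whose cursor is displaced laterally by a shift
drawn from a Gaussian prior (mean 1 cm rightward, SD 0.5 cm). The only
evidence about the current shift is a 100 ms midpoint flash whose
reliability takes one of four levels, scheduled 3:1:1:1 in exact
1080-trial blocks: clear (σ₀), moderate cloud SD 1 cm (σ_M), large cloud
SD 2 cm (σ_L), or no feedback at all (σ∞). Three observer strategies are
implemented:

* **full compensation** — cancel the sensed shift; cursor-error slope 0;
* **minimal mapping** — apply one learned constant always; slope 1 through
  the prior mean;
* **Bayesian estimation** — cancel the reliability-weighted posterior mean

  μ_est = σ_s²/(σ_s²+σ_p²)·μ_prior + σ_p²/(σ_s²+σ_p²)·x_sensed,

  giving a cursor-error slope σ_s²/(σ_s²+σ_p²) ∈ (0, 1) that grows with
  sensory noise and always crosses zero at the prior mean. On no-feedback
  trials the estimate collapses onto the learned prior — which makes σ∞
  endpoints the clean behavioural readout of the prior.

Interlimb generalization is quantified as
100 · (mean early left-hand σ∞ endpoints) / (mean late right-hand σ∞
endpoints), using the trial-980–1080 and 1080–1180 windows.

## Worked example

Simulate one converged Bayesian subject through a 2160-trial baseline
session and run the standard analyses:

```r
library(reachprior)
d <- make_design("BSL", seed = 42)
s <- generate_subject(d, observer_params("BAYES"), seed = 43,
                      subject_id = "sim01")

mean_endpoint(sigma_inf_endpoints(s, c(1081, 2160)))
#> Endpoint: mean -1.018 cm, SD 0.270 cm (n = 180)

cursor_error_slopes(s, c(1081, 2160))
#> Cursor-error slope fits (per uncertainty condition):
#>     level  slope intercept_cm abscissa_crossing_cm   n degenerate
#>      ZERO 0.0612       -0.069                1.127 540      FALSE
#>  MODERATE 0.7794       -0.789                1.012 180      FALSE
#>     LARGE 0.9363       -0.930                0.994 180      FALSE
#>  INFINITE 1.0015       -1.020                1.018 180      FALSE
```

The no-feedback endpoints sit ~1 cm left of the target — the observer has
the prior and leans on it fully when there is no evidence — and the fitted
slopes climb with sensory noise toward the predicted
σ_s²/(σ_s²+σ_p²) values (0.04, 0.80, 0.94 for σ_s = 0.1, 1, 2 at
σ_p = 0.5), each line crossing the abscissa near the 1 cm prior mean.

Transfer to the untrained arm:

```r
ce <- generate_subject(make_design("CE", seed = 44),
                       observer_params("BAYES"), seed = 45)
interlimb_generalization(ce)
#> Generalization: 103.5% (signed 103.5%)
#>   early LH: -0.988 cm (n = 21); late RH: -0.955 cm (n = 19)
```

An extrinsically coded observer transfers fully in the congruent-extrinsic
design (~100%); in the congruent-intrinsic design its endpoints land on the
wrong side of the mirrored perturbation and the signed generalization is
~−100%. The sign conventions, model assumptions, and all tunable
parameters are documented in
`vignettes/bayesian-visuomotor-learning.Rmd`.

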