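#' Observer model parameters
#'
#' Configures one of the three candidate observer models:
#' \describe{
#'   \item{FULL_COMP}{full compensation -- cancels the sensed shift exactly;
#'     increasing feedback uncertainty inflates endpoint variance without
#'     changing the mean (zero cursor-error slope).}
#'   \item{MINIMAL_MAP}{minimal mapping -- applies one fixed learned
#'     compensation (the running estimate of the prior mean) on every trial
#'     regardless of the current feedback (unit cursor-error slope through
#'     the prior mean).}
#'   \item{BAYES}{Bayesian estimation -- combines the learned prior with the
#'     sensed shift, weighting each by its relative reliability.}
#' }
#'
#' `sigma_s_by_level` maps each uncertainty condition to the observer's
#' effective sensory noise SD; `INFINITE` must be `NA` (no sensed value).
#' The defaults use the point-cloud SDs as effective sensory SDs
#' (ZERO = 0.1, MODERATE = 1, LARGE = 2 cm); the task manipulates but never
#' calibrates these, so they are fully configurable.
#'
#' By default the observer is *converged*: its prior-mean estimate starts at
#' the true prior mean (1 cm) with small residual uncertainty and learning is
#' disabled. Set `learning_enabled = TRUE` (and, typically,
#' `initial_prior_mean_cm = 0` with a large `initial_prior_uncertainty_cm`)
#' to simulate acquisition with the Kalman-style rule of
#' [update_prior_estimate()].
#'
#' @param model `"BAYES"`, `"FULL_COMP"` or `"MINIMAL_MAP"`.
#' @param sigma_p_cm Prior SD used by the observer (cm, > 0).
#' @param sigma_s_by_level Named numeric vector of sensory noise SDs per
#'   condition label; `INFINITE` must be `NA`.
#' @param motor_noise_sd_cm Additive Gaussian execution noise on the realized
#'   endpoint (cm, >= 0). Default 0.3.
#' @param frame `"EXTRINSIC"` (screen-based) or `"INTRINSIC"` (joint-based)
#'   coding of the perturbation; see [encode_in_frame()].
#' @param learning_enabled Update the prior-mean estimate trial by trial?
#' @param initial_prior_mean_cm Starting prior-mean estimate (cm).
#' @param initial_prior_uncertainty_cm Starting SD of that estimate (cm).
#' @return An object of class `"observer_params"`.
#' @examples
#' observer_params("BAYES")                       # converged Bayesian observer
#' observer_params("MINIMAL_MAP", motor_noise_sd_cm = 0)
#' @export
observer_params <- function(model = c("BAYES", "FULL_COMP", "MINIMAL_MAP"),
                            sigma_p_cm = 0.5,
                            sigma_s_by_level = c(ZERO = 0.1, MODERATE = 1,
                                                 LARGE = 2, INFINITE = NA_real_),
                            motor_noise_sd_cm = 0.3,
                            frame = c("EXTRINSIC", "INTRINSIC"),
                            learning_enabled = FALSE,
                            initial_prior_mean_cm = 1,
                            initial_prior_uncertainty_cm = 0.05) {
  model <- match.arg(model)
  frame <- match.arg(frame)
  stopifnot(sigma_p_cm > 0, motor_noise_sd_cm >= 0,
            initial_prior_uncertainty_cm >= 0)
  missing_lv <- setdiff(level_labels(), names(sigma_s_by_level))
  if (length(missing_lv)) {
    stop("`sigma_s_by_level` must name every condition; missing: ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  if (!is.na(sigma_s_by_level[["INFINITE"]])) {
    stop("`sigma_s_by_level[\"INFINITE\"]` must be NA: no-feedback trials ",
         "never yield a sensed value", call. = FALSE)
  }
  finite_s <- sigma_s_by_level[setdiff(level_labels(), "INFINITE")]
  if (any(is.na(finite_s)) || any(finite_s < 0)) {
    stop("sensory noise SDs must be >= 0 for feedback conditions",
         call. = FALSE)
  }
  structure(list(model = model, sigma_p_cm = sigma_p_cm,
                 sigma_s_by_level = sigma_s_by_level,
                 motor_noise_sd_cm = motor_noise_sd_cm, frame = frame,
                 learning_enabled = learning_enabled,
                 initial_prior_mean_cm = initial_prior_mean_cm,
                 initial_prior_uncertainty_cm = initial_prior_uncertainty_cm),
            class = "observer_params")
}

#' Observer internal state
#'
#' The running estimate of the mean of the shift distribution and the SD of
#' that estimate.
#'
#' @param prior_mean_estimate_cm Current prior-mean estimate (cm).
#' @param prior_uncertainty_cm SD of the estimate (cm, >= 0).
#' @return An object of class `"observer_state"`.
#' @export
observer_state <- function(prior_mean_estimate_cm, prior_uncertainty_cm) {
  stopifnot(prior_uncertainty_cm >= 0)
  structure(list(prior_mean_estimate_cm = prior_mean_estimate_cm,
                 prior_uncertainty_cm = prior_uncertainty_cm),
            class = "observer_state")
}

#' @rdname observer_state
#' @param params An [observer_params()] object.
#' @export
initial_state <- function(params) {
  observer_state(params$initial_prior_mean_cm,
                 params$initial_prior_uncertainty_cm)
}

#' Sense the shift on one trial
#'
#' The observer's noisy measurement of the imposed lateral shift from the
#' midpoint feedback: the true shift plus independent Gaussian noise with
#' the condition's sensory SD. No-feedback (`INFINITE`) trials yield an
#' absent value (`NA`).
#'
#' @param true_shift_cm Imposed shift (cm), in the observer's coding frame.
#' @param level Condition label.
#' @param params [observer_params()].
#' @param seed Optional integer seed.
#' @return An object of class `"sensed_shift"` with fields `value_cm`
#'   (`NA` when absent) and `level`.
#' @export
sense_shift <- function(true_shift_cm, level, params, seed = NULL) {
  check_level(level)
  sigma_s <- params$sigma_s_by_level[[level]]
  value <- if (is.na(sigma_s)) {
    NA_real_
  } else if (sigma_s == 0) {
    true_shift_cm
  } else {
    with_seed_if(seed, true_shift_cm + rnorm(1, 0, sigma_s))
  }
  structure(list(value_cm = value, level = level), class = "sensed_shift")
}

sensed_value <- function(sensed) {
  if (inherits(sensed, "sensed_shift")) sensed$value_cm else as.numeric(sensed)
}

#' Reliability-weighted estimate of the imposed shift
#'
#' The posterior mean under Gaussian prior and likelihood: the prior mean and
#' the sensed value, each weighted by the *other* source's variance relative
#' to the total,
#' \deqn{\mu = \frac{\sigma_s^2}{\sigma_s^2+\sigma_p^2}\,\mu_{prior}
#'          + \frac{\sigma_p^2}{\sigma_s^2+\sigma_p^2}\,x_{sensed}.}
#' With an absent sensed value (flat likelihood) the estimate is the prior
#' mean; with noiseless evidence (`sigma_s = 0`) it is the sensed value.
#'
#' @param sensed A `"sensed_shift"` or a bare numeric (use `NA` for absent).
#' @param prior_mean_cm Mean of the learned prior (cm).
#' @param sigma_p_cm Prior SD (cm, > 0).
#' @param sigma_s_cm Sensory noise SD (cm); `NA`/`Inf` mean absent evidence.
#' @return The posterior-mean estimate (cm).
#' @examples
#' bayes_estimate(2, prior_mean_cm = 1, sigma_p_cm = 1, sigma_s_cm = 1)  # 1.5
#' @export
bayes_estimate <- function(sensed, prior_mean_cm, sigma_p_cm, sigma_s_cm) {
  x <- sensed_value(sensed)
  if (is.na(x) || is.na(sigma_s_cm) || is.infinite(sigma_s_cm)) {
    return(prior_mean_cm)
  }
  if (sigma_p_cm <= 0 && sigma_s_cm <= 0) {
    if (isTRUE(all.equal(x, prior_mean_cm))) return(prior_mean_cm)
    stop("undefined weighting: both sigma_p and sigma_s are zero and the ",
         "sensed value differs from the prior mean", call. = FALSE)
  }
  s2 <- sigma_s_cm^2
  p2 <- sigma_p_cm^2
  (s2 / (s2 + p2)) * prior_mean_cm + (p2 / (s2 + p2)) * x
}

#' Posterior variance of the shift estimate
#'
#' The joint variance of prior and likelihood,
#' \eqn{\sigma_{sp}^2 = \sigma_s^2\sigma_p^2 / (\sigma_s^2+\sigma_p^2)},
#' never larger than either component variance. Absent evidence
#' (`NA`/`Inf` sensory SD) returns the prior variance.
#'
#' @param sigma_s_cm,sigma_p_cm Sensory and prior SDs (cm); their sum must
#'   be positive.
#' @return Posterior variance (cm^2).
#' @export
posterior_variance <- function(sigma_s_cm, sigma_p_cm) {
  if (is.na(sigma_s_cm) || is.infinite(sigma_s_cm)) return(sigma_p_cm^2)
  if (sigma_s_cm + sigma_p_cm <= 0) {
    stop("at least one of sigma_s, sigma_p must be positive", call. = FALSE)
  }
  (sigma_s_cm^2 * sigma_p_cm^2) / (sigma_s_cm^2 + sigma_p_cm^2)
}

#' Predicted cursor-error slope for a Bayesian observer
#'
#' For a converged Bayesian observer, expected cursor error is
#' `slope * (x_true - prior_mean)` with
#' \eqn{slope = \sigma_s^2/(\sigma_s^2+\sigma_p^2)}, so the error-vs-shift
#' line crosses zero at the prior mean and steepens with feedback
#' uncertainty: 0 at noiseless feedback (full compensation limit) and 1 with
#' absent feedback (minimal-mapping-like reliance on the prior).
#'
#' @param sigma_s_cm Sensory noise SD (cm); `NA`/`Inf` for absent feedback.
#'   Vectorized.
#' @param sigma_p_cm Prior SD (cm).
#' @return Slope(s) in `[0, 1]`.
#' @examples
#' predicted_error_slope(c(0.1, 1, 2, NA), 0.5)
#' @export
predicted_error_slope <- function(sigma_s_cm, sigma_p_cm) {
  out <- rep(1, length(sigma_s_cm))
  ok <- !is.na(sigma_s_cm) & is.finite(sigma_s_cm)
  if (any(ok)) {
    s2 <- sigma_s_cm[ok]^2
    if (any(s2 + sigma_p_cm^2 <= 0)) {
      stop("sigma_s^2 + sigma_p^2 must be positive", call. = FALSE)
    }
    out[ok] <- s2 / (s2 + sigma_p_cm^2)
  }
  out
}

#' Plan the lateral compensation for one trial
#'
#' The intended lateral aim offset, i.e. minus the observer's estimate of
#' the imposed shift: full compensation cancels the sensed value (falling
#' back on the prior-mean estimate when no feedback is shown), minimal
#' mapping always applies the learned constant, and the Bayesian observer
#' cancels its reliability-weighted posterior estimate.
#'
#' @param model Observer model name (usually `params$model`).
#' @param sensed A `"sensed_shift"`.
#' @param state An `"observer_state"`.
#' @param params [observer_params()].
#' @return Intended lateral aim offset (cm) in the observer's coding frame.
#' @export
plan_compensation <- function(model, sensed, state, params) {
  x <- sensed_value(sensed)
  switch(model,
    FULL_COMP = if (is.na(x)) -state$prior_mean_estimate_cm else -x,
    MINIMAL_MAP = -state$prior_mean_estimate_cm,
    BAYES = {
      sigma_s <- params$sigma_s_by_level[[sensed$level]]
      -bayes_estimate(x, state$prior_mean_estimate_cm, params$sigma_p_cm,
                      sigma_s)
    },
    stop("unknown observer model: ", model, call. = FALSE)
  )
}

#' Update the running prior-mean estimate
#'
#' Kalman-style precision weighting: the sensed shift is treated as a noisy
#' observation of the prior mean with observation SD `sigma_s_cm`; the gain
#' is the estimate's variance over the total, and the estimate's uncertainty
#' shrinks (never grows) with each update. Absent observations leave the
#' state unchanged. The steady-state behaviour -- the estimate converging on
#' the true prior mean -- is all downstream analyses rely on; the trajectory
#' of acquisition is a modelling convenience.
#'
#' @param state An `"observer_state"`.
#' @param sensed A `"sensed_shift"` (or numeric; `NA` = absent).
#' @param sigma_s_cm Observation noise SD for this condition (cm).
#' @return The updated `"observer_state"`.
#' @export
update_prior_estimate <- function(state, sensed, sigma_s_cm) {
  x <- sensed_value(sensed)
  if (is.na(x) || is.na(sigma_s_cm)) return(state)
  u2 <- state$prior_uncertainty_cm^2
  denom <- u2 + sigma_s_cm^2
  gain <- if (denom == 0) 0 else u2 / denom
  observer_state(
    state$prior_mean_estimate_cm + gain * (x - state$prior_mean_estimate_cm),
    sqrt((1 - gain) * u2)
  )
}

#' Transform a lateral value between coding frames
#'
#' Extrinsic (screen-based) coding is the identity for both hands. Intrinsic
#' (joint-based) coding flips the sign of lateral values for the left hand:
#' a rightward shift for the right arm and a leftward shift for the left arm
#' both demand elbow flexion, so they are the *same* perturbation in
#' intrinsic coordinates. The transform is its own inverse.
#'
#' @param lateral_value_cm Signed lateral value(s) (cm). Vectorized, as is
#'   `hand`.
#' @param hand `"RH"` or `"LH"`.
#' @param frame `"EXTRINSIC"` or `"INTRINSIC"`.
#' @return Transformed lateral value(s) (cm).
#' @examples
#' encode_in_frame(1, "LH", "INTRINSIC")   # -1
#' encode_in_frame(1, "LH", "EXTRINSIC")   # +1
#' @export
encode_in_frame <- function(lateral_value_cm, hand, frame) {
  check_hand(hand)
  if (length(frame) != 1L || !frame %in% c("EXTRINSIC", "INTRINSIC")) {
    stop("`frame` must be \"EXTRINSIC\" or \"INTRINSIC\"", call. = FALSE)
  }
  if (frame == "EXTRINSIC") {
    lateral_value_cm
  } else {
    ifelse(hand == "LH", -lateral_value_cm, lateral_value_cm)
  }
}
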