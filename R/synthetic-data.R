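# Quintic minimum-jerk position profile on normalized time s in [0, 1].
min_jerk_profile <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

#' Synthesize one 200 Hz reach trajectory
#'
#' A two-segment kinematic stand-in for a robot-recorded reach. The
#' longitudinal (y) profile is minimum-jerk from 0 to the reach extent
#' (nominally 20 cm); the lateral (x) profile follows its own minimum-jerk
#' ramp to `first_half_aim_x` over the first half of the movement, then
#' smoothly re-aims to the final lateral position over the second half --
#' mirroring a plan made from the prior before the midpoint feedback and a
#' correction made after it. The realized endpoint is
#' `second_half_aim_x` plus Gaussian motor noise; terminal speed is zero by
#' construction (well under 5% of the minimum-jerk peak of
#' `1.875 * extent / duration`). Samples are spaced 5 ms apart (200 Hz).
#'
#' A `reach_extent_cm` below the 19 cm offset-detection criterion produces a
#' short, incomplete reach, i.e. a trial that will time out.
#'
#' @param first_half_aim_x Lateral aim before midpoint feedback (cm, screen).
#' @param second_half_aim_x Lateral aim after midpoint feedback (cm, screen).
#' @param duration_ms Movement duration, in (0, 4000]. Default 800.
#' @param motor_noise_sd_cm SD of the endpoint execution noise (cm).
#' @param seed Optional integer seed.
#' @param dt_ms Sample spacing; 5 ms = 200 Hz.
#' @param reach_extent_cm Longitudinal extent actually covered (cm).
#' @return A data.frame of class `"trajectory"` with columns `t_ms`, `x_cm`,
#'   `y_cm`.
#' @examples
#' tr <- synth_trajectory(0, -1, motor_noise_sd_cm = 0)
#' tail(tr, 1)   # endpoint at (-1, 20)
#' @export
synth_trajectory <- function(first_half_aim_x, second_half_aim_x,
                             duration_ms = 800, motor_noise_sd_cm = 0.3,
                             seed = NULL, dt_ms = 5, reach_extent_cm = 20) {
  stopifnot(duration_ms > 0, duration_ms <= 4000, dt_ms > 0,
            reach_extent_cm > 0)
  t <- seq(0, duration_ms, by = dt_ms)
  if (t[length(t)] < duration_ms) t <- c(t, duration_ms)
  y <- reach_extent_cm * min_jerk_profile(t / duration_ms)
  noise <- with_seed_if(seed, {
    if (motor_noise_sd_cm > 0) rnorm(1, 0, motor_noise_sd_cm) else 0
  })
  xf <- second_half_aim_x + noise
  half <- duration_ms / 2
  first <- t <= half
  x <- numeric(length(t))
  x[first] <- first_half_aim_x * min_jerk_profile(t[first] / half)
  x[!first] <- first_half_aim_x +
    (xf - first_half_aim_x) * min_jerk_profile((t[!first] - half) / half)
  out <- data.frame(t_ms = t, x_cm = x, y_cm = y)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Simulate a full synthetic subject
#'
#' Runs an observer model through an experiment design trial by trial:
#' encode the imposed shift into the observer's coding frame, sense it under
#' the trial's uncertainty condition, aim the first half of the reach from
#' the current prior-mean estimate and the second half from the planned
#' compensation, synthesize the trajectory, recover the endpoint with the
#' movement-offset criterion of [detect_movement_offset()], and (optionally)
#' update the prior-mean estimate. Left-hand trials are handled through the
#' frame transform in both directions (perceive and act), so an intrinsic
#' observer transfers its learned compensation mirrored about the midline.
#'
#' Learning updates (when `params$learning_enabled`) use every sensed trial
#' for the Bayesian and full-compensation observers, but only `ZERO` trials
#' for minimal mapping, since endpoint error feedback -- the only signal that
#' model can learn from -- is given in that condition alone.
#'
#' @param design An `"experiment_design"` (or bare trial table with columns
#'   `index`, `phase`, `hand`, `level`, `true_shift_cm`).
#' @param params [observer_params()].
#' @param seed Optional integer seed; fixes the whole session.
#' @param subject_id Identifier recorded in the trial log.
#' @param duration_ms Movement duration per reach. Default 800 ms.
#' @param keep_trajectories Keep the full 200 Hz sample table (one row per
#'   sample per trial)? Default `FALSE`; endpoints are always extracted from
#'   the synthesized trajectories either way.
#' @param timeout_trials Trial indices simulated as incomplete reaches
#'   (stopping short of the 19 cm criterion), flagged as timeouts.
#' @return An object of class `"subject_dataset"`: `subject_id`, `group`
#'   (design name), `baseline_bias_cm` (named per hand), `trials` (one row
#'   per trial with endpoint and timeout columns), `trajectories` (sample
#'   table or NULL), and `final_state` (the observer state after the last
#'   trial).
#' @examples
#' d <- single_level_design(50, "INFINITE", seed = 1)
#' s <- generate_subject(d, observer_params("BAYES"), seed = 2)
#' mean(s$trials$endpoint_x_cm)   # near -1: the learned prior, read out
#' @export
generate_subject <- function(design, params, seed = NULL, subject_id = "S1",
                             duration_ms = 800, keep_trajectories = FALSE,
                             timeout_trials = integer(0)) {
  trials <- as_trials(design)
  group <- if (inherits(design, "experiment_design")) design$name else "CUSTOM"
  stopifnot(inherits(params, "observer_params"))
  n <- nrow(trials)
  lev <- trials$level
  hands <- trials$hand
  shifts <- trials$true_shift_cm

  with_seed_if(seed, {
    state <- initial_state(params)
    ep_x <- ep_y <- rep(NA_real_, n)
    tmo <- logical(n)
    traj_list <- if (keep_trajectories) vector("list", n)
    for (i in seq_len(n)) {
      shift_f <- encode_in_frame(shifts[i], hands[i], params$frame)
      sensed <- sense_shift(shift_f, lev[i], params)
      aim1_f <- -state$prior_mean_estimate_cm
      aim2_f <- plan_compensation(params$model, sensed, state, params)
      aim1 <- encode_in_frame(aim1_f, hands[i], params$frame)
      aim2 <- encode_in_frame(aim2_f, hands[i], params$frame)
      extent <- if (i %in% timeout_trials) 15 else 20
      traj <- synth_trajectory(aim1, aim2, duration_ms,
                               params$motor_noise_sd_cm,
                               reach_extent_cm = extent)
      off <- detect_movement_offset(traj)
      tmo[i] <- !off$valid
      if (off$valid) {
        ep_x[i] <- off$endpoint_x_cm
        ep_y[i] <- off$endpoint_y_cm
      }
      if (keep_trajectories) {
        traj_list[[i]] <- cbind(index = trials$index[i],
                                as.data.frame(traj))
      }
      if (params$learning_enabled && !is.na(sensed$value_cm)) {
        if (params$model != "MINIMAL_MAP" || lev[i] == "ZERO") {
          state <- update_prior_estimate(state, sensed,
                                         params$sigma_s_by_level[[lev[i]]])
        }
      }
    }
    log <- data.frame(
      subject_id = subject_id, group = group,
      index = trials$index, phase = trials$phase, hand = hands,
      level = lev, true_shift_cm = shifts,
      endpoint_x_cm = ep_x, endpoint_y_cm = ep_y, timeout = tmo,
      stringsAsFactors = FALSE
    )
    structure(list(
      subject_id = subject_id, group = group,
      baseline_bias_cm = c(RH = 0, LH = 0),
      trials = log,
      trajectories = if (keep_trajectories) do.call(rbind, traj_list),
      final_state = state
    ), class = "subject_dataset")
  })
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d trials, %d timeouts\n", x$subject_id,
              x$group, nrow(x$trials), sum(x$trials$timeout)))
  cat(sprintf("  prior-mean estimate after last trial: %.3f cm\n",
              x$final_state$prior_mean_estimate_cm))
  invisible(x)
}

trial_log_columns <- c("subject_id", "group", "index", "phase", "hand",
                       "level", "true_shift_cm", "endpoint_x_cm",
                       "endpoint_y_cm", "timeout")

#' Write and read trial logs
#'
#' The trial log is a tab-delimited UTF-8 table with one row per trial and
#' columns `subject_id`, `group`, `index`, `phase`, `hand`, `level`,
#' `true_shift_cm`, `endpoint_x_cm`, `endpoint_y_cm`, `timeout`. Trajectory
#' samples go to a sidecar table (`index`, `t_ms`, `x_cm`, `y_cm`) keyed by
#' trial index via [write_trajectories()]. The round trip is lossless to
#' full numeric precision.
#'
#' @param dataset A `"subject_dataset"`.
#' @param path File path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   a `"subject_dataset"`.
#' @export
write_trial_log <- function(dataset, path) {
  stopifnot(inherits(dataset, "subject_dataset"))
  log <- dataset$trials[, trial_log_columns]
  log$true_shift_cm <- format(log$true_shift_cm, digits = 17, trim = TRUE)
  log$endpoint_x_cm <- format(log$endpoint_x_cm, digits = 17, trim = TRUE)
  log$endpoint_y_cm <- format(log$endpoint_y_cm, digits = 17, trim = TRUE)
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @param trajectories_path Optional path of a samples sidecar written by
#'   [write_trajectories()].
#' @export
read_trial_log <- function(path, trajectories_path = NULL) {
  log <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(trial_log_columns, names(log))
  if (length(missing)) {
    stop("trial log is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(log$index != seq_len(nrow(log)))) {
    stop("trial `index` must be contiguous starting at 1", call. = FALSE)
  }
  traj <- NULL
  if (!is.null(trajectories_path)) {
    traj <- read.delim(trajectories_path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
    tmiss <- setdiff(c("index", "t_ms", "x_cm", "y_cm"), names(traj))
    if (length(tmiss)) {
      stop("trajectory sidecar is missing required column(s): ",
           paste(tmiss, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    subject_id = log$subject_id[1], group = log$group[1],
    baseline_bias_cm = c(RH = 0, LH = 0),
    trials = log, trajectories = traj, final_state = NULL
  ), class = "subject_dataset")
}

#' @rdname write_trial_log
#' @export
write_trajectories <- function(dataset, path) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (is.null(dataset$trajectories)) {
    stop("dataset holds no trajectories; simulate with ",
         "`keep_trajectories = TRUE`", call. = FALSE)
  }
  write.table(dataset$trajectories, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Add a constant directional bias to one hand's endpoints
#'
#' Emulates a subject's pre-existing directional reach bias, which the
#' target's spatial tolerance can leave uncorrected through the experiment.
#' The bias is recorded in the dataset metadata so a later baseline
#' correction can be checked against it.
#'
#' @param dataset A `"subject_dataset"`.
#' @param bias_cm Named numeric, e.g. `c(RH = -0.35)`; each entry is added
#'   to all endpoints of that hand.
#' @param max_bias_cm Largest admissible magnitude; defaults to the 1 cm
#'   target radius.
#' @return The biased `"subject_dataset"`.
#' @export
inject_baseline_bias <- function(dataset, bias_cm, max_bias_cm = 1) {
  stopifnot(inherits(dataset, "subject_dataset"), is.numeric(bias_cm))
  check_hand(names(bias_cm))
  if (any(abs(bias_cm) > max_bias_cm)) {
    stop("|bias| must not exceed ", max_bias_cm,
         " cm (the target radius); raise `max_bias_cm` to override",
         call. = FALSE)
  }
  for (h in names(bias_cm)) {
    sel <- dataset$trials$hand == h & !dataset$trials$timeout
    dataset$trials$endpoint_x_cm[sel] <-
      dataset$trials$endpoint_x_cm[sel] + bias_cm[[h]]
    dataset$baseline_bias_cm[h] <- dataset$baseline_bias_cm[h] + bias_cm[[h]]
  }
  dataset
}
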