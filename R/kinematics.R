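#' Tangential speed along a trajectory
#'
#' Central finite differences on interior samples and one-sided differences
#' at the ends, combining the x and y components into tangential speed.
#' Works on non-uniform time grids. An optional centred moving-average
#' smoother is available (off by default); end samples are left unsmoothed.
#'
#' @param trajectory A data.frame with columns `t_ms`, `x_cm`, `y_cm` and at
#'   least 3 samples.
#' @param smooth_window Odd window length in samples for the optional moving
#'   average; `0` (default) disables smoothing.
#' @return Numeric vector of speeds in cm/s, one per sample.
#' @export
compute_speed <- function(trajectory, smooth_window = 0) {
  t <- trajectory$t_ms
  x <- trajectory$x_cm
  y <- trajectory$y_cm
  n <- length(t)
  if (n < 3L) stop("need at least 3 samples to estimate speed", call. = FALSE)
  vx <- vy <- numeric(n)
  i <- 2:(n - 1L)
  vx[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  vy[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1])
  vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  vy[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  speed <- sqrt(vx^2 + vy^2) * 1000   # cm/ms -> cm/s
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) {
      stop("`smooth_window` must be odd", call. = FALSE)
    }
    sm <- as.numeric(stats::filter(speed, rep(1 / smooth_window,
                                              smooth_window), sides = 2))
    speed <- ifelse(is.na(sm), speed, sm)
  }
  speed
}

#' Detect movement offset by the combined spatial and velocity criterion
#'
#' Movement offset is the first sample at which speed drops strictly below
#' 5% of peak speed *after* the hand has covered at least 19 cm of the
#' 20 cm reach along y. The spatial clause guarantees the slow samples at
#' the start of the trial (also below threshold) are never selected. If no
#' sample qualifies within the 4000 ms allowed per reach, the trial is
#' invalid (timeout semantics) and the endpoint is undefined.
#'
#' @param trajectory A trajectory data.frame (`t_ms`, `x_cm`, `y_cm`).
#' @param min_reach_cm Minimum longitudinal displacement before offset can
#'   be declared. Default 19.
#' @param speed_fraction Fraction of peak speed defining the threshold
#'   (strict `<`). Default 0.05.
#' @param max_time_ms Time limit per reach. Default 4000.
#' @param smooth_window Passed to [compute_speed()].
#' @return An object of class `"offset_result"`: `offset_time_ms`,
#'   `endpoint_x_cm`, `endpoint_y_cm`, `peak_speed_cm_per_s`, `valid`.
#' @export
detect_movement_offset <- function(trajectory, min_reach_cm = 19,
                                   speed_fraction = 0.05, max_time_ms = 4000,
                                   smooth_window = 0) {
  speed <- compute_speed(trajectory, smooth_window = smooth_window)
  within <- trajectory$t_ms <= max_time_ms
  peak <- max(speed[within])
  ok <- within & speed < speed_fraction * peak &
    trajectory$y_cm >= min_reach_cm
  idx <- which(ok)[1]
  if (is.na(idx)) {
    return(structure(list(offset_time_ms = NA_real_,
                          endpoint_x_cm = NA_real_, endpoint_y_cm = NA_real_,
                          peak_speed_cm_per_s = peak, valid = FALSE),
                     class = "offset_result"))
  }
  structure(list(offset_time_ms = trajectory$t_ms[idx],
                 endpoint_x_cm = trajectory$x_cm[idx],
                 endpoint_y_cm = trajectory$y_cm[idx],
                 peak_speed_cm_per_s = peak, valid = TRUE),
            class = "offset_result")
}

#' @export
print.offset_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Movement offset at %g ms: endpoint (%.3f, %.3f) cm; peak speed %.1f cm/s\n",
                x$offset_time_ms, x$endpoint_x_cm, x$endpoint_y_cm,
                x$peak_speed_cm_per_s))
  } else {
    cat("No movement offset detected (timeout)\n")
  }
  invisible(x)
}

#' Reach endpoint at movement offset
#'
#' The x and y position at the movement-offset sample, unmodified.
#'
#' @inheritParams detect_movement_offset
#' @param ... Passed to [detect_movement_offset()].
#' @return Named numeric `c(x_cm =, y_cm =)`.
#' @export
extract_endpoint <- function(trajectory, ...) {
  off <- detect_movement_offset(trajectory, ...)
  if (!off$valid) {
    stop("no movement offset within the time limit; trial timed out",
         call. = FALSE)
  }
  c(x_cm = off$endpoint_x_cm, y_cm = off$endpoint_y_cm)
}
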