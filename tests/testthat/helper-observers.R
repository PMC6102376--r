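# Shared fixtures: converged observers and small probe simulations.

converged <- function(model, ...) {
  observer_params(model, learning_enabled = FALSE,
                  initial_prior_mean_cm = 1,
                  initial_prior_uncertainty_cm = 0, ...)
}

# Brute-force movement-offset oracle: plain loop over every sample, applying
# the spatial + velocity criterion literally. Velocities by the same
# finite-difference scheme, computed sample by sample.
offset_oracle <- function(traj, min_reach = 19, frac = 0.05,
                          max_time = 4000) {
  n <- nrow(traj)
  sp <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    vx <- (traj$x_cm[hi] - traj$x_cm[lo]) / (traj$t_ms[hi] - traj$t_ms[lo])
    vy <- (traj$y_cm[hi] - traj$y_cm[lo]) / (traj$t_ms[hi] - traj$t_ms[lo])
    sp[i] <- sqrt(vx^2 + vy^2) * 1000
  }
  peak <- max(sp[traj$t_ms <= max_time])
  for (i in seq_len(n)) {
    if (traj$t_ms[i] <= max_time && sp[i] < frac * peak &&
        traj$y_cm[i] >= min_reach) {
      return(list(idx = i, t = traj$t_ms[i], x = traj$x_cm[i],
                  y = traj$y_cm[i], valid = TRUE))
    }
  }
  list(idx = NA, valid = FALSE)
}
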