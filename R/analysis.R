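#' No-feedback endpoints within a trial range
#'
#' The primary behavioural readout of the learned prior: lateral endpoints
#' of the no-midpoint-feedback (`INFINITE`) trials, which are uncontaminated
#' by current sensory evidence. Timeout trials are excluded. Trial ranges
#' are 1-based and inclusive on both ends, so the conventional "trials
#' 980--1080" window selects 101 trials.
#'
#' @param dataset A `"subject_dataset"` (or its trial table).
#' @param trial_range Length-2 inclusive range `c(a, b)`.
#' @return Numeric vector of endpoint x values (cm), in trial order;
#'   possibly empty.
#' @export
sigma_inf_endpoints <- function(dataset, trial_range) {
  trials <- as_trials(dataset)
  stopifnot(length(trial_range) == 2L, trial_range[1] <= trial_range[2])
  if (trial_range[1] < 1 || trial_range[2] > max(trials$index)) {
    stop("`trial_range` must lie within the dataset's trial indices",
         call. = FALSE)
  }
  sel <- trials$level == "INFINITE" & !trials$timeout &
    trials$index >= trial_range[1] & trials$index <= trial_range[2]
  trials$endpoint_x_cm[sel][order(trials$index[sel])]
}

#' Summarize endpoints
#'
#' Arithmetic mean and sample SD of a set of endpoints.
#'
#' @param endpoints Non-empty numeric vector of endpoint x values (cm).
#' @return An object of class `"endpoint_summary"`: `mean_cm`, `sd_cm`, `n`.
#' @examples
#' mean_endpoint(c(-2, 0))   # mean -1, sd sqrt(2)
#' @export
mean_endpoint <- function(endpoints) {
  endpoints <- endpoints[!is.na(endpoints)]
  if (length(endpoints) < 1L) {
    stop("cannot summarize an empty endpoint set", call. = FALSE)
  }
  structure(list(mean_cm = mean(endpoints),
                 sd_cm = if (length(endpoints) > 1L) sd(endpoints) else NA_real_,
                 n = length(endpoints)),
            class = "endpoint_summary")
}

#' @export
print.endpoint_summary <- function(x, ...) {
  cat(sprintf("Endpoint: mean %.3f cm, SD %.3f cm (n = %d)\n",
              x$mean_cm, x$sd_cm, x$n))
  invisible(x)
}

summary_mean <- function(x) {
  if (inherits(x, "endpoint_summary")) x$mean_cm else as.numeric(x)
}

as_endpoint_summary <- function(x) {
  if (inherits(x, "endpoint_summary")) return(x)
  structure(list(mean_cm = as.numeric(x), sd_cm = NA_real_, n = NA_integer_),
            class = "endpoint_summary")
}

#' Baseline-correct endpoints
#'
#' Subtracts a hand's baseline directional bias -- the mean endpoint from
#' no-shift, no-feedback reaches with the same hand -- from each endpoint.
#'
#' @param endpoints Numeric endpoint x values (cm).
#' @param baseline An `"endpoint_summary"` (or a bare mean, in cm) from the
#'   baseline trials.
#' @return Corrected endpoints.
#' @examples
#' baseline_correct(-1.51, -0.35)   # -1.16
#' @export
baseline_correct <- function(endpoints, baseline) {
  endpoints - summary_mean(baseline)
}

#' Cursor error versus imposed shift, fitted per uncertainty condition
#'
#' Cursor error is the lateral deviation of the (shifted) cursor from the
#' target at movement offset: `endpoint_x + imposed_shift - target_x`. Its
#' slope against the imposed shift indexes reliance on the prior: 0 for full
#' compensation, 1 (crossing zero at the prior mean) for minimal mapping,
#' and \eqn{\sigma_s^2/(\sigma_s^2+\sigma_p^2)} for a Bayesian observer.
#' The fit is ordinary least squares on trial-level points; means over
#' equal-count bins of imposed shift are reported alongside for display
#' (`attr(result, "bins")`).
#'
#' @param dataset A `"subject_dataset"` (or trial table).
#' @param trial_range Inclusive trial range.
#' @param n_bins Number of equal-count shift bins for the display summary.
#'   Default 11.
#' @param target_x Lateral target position (cm); 0 in the standard frame.
#' @return A data.frame of class `"slope_fits"` with one row per condition:
#'   `level`, `slope`, `intercept_cm`, `abscissa_crossing_cm`
#'   (`-intercept/slope`), `n`, `degenerate`. Conditions with fewer than two
#'   distinct shift values are flagged degenerate and left unfitted.
#' @export
cursor_error_slopes <- function(dataset, trial_range, n_bins = 11,
                                target_x = 0) {
  trials <- as_trials(dataset)
  stopifnot(length(trial_range) == 2L, trial_range[1] <= trial_range[2])
  keep <- !trials$timeout & trials$index >= trial_range[1] &
    trials$index <= trial_range[2] & !is.na(trials$endpoint_x_cm)
  trials <- trials[keep, ]
  trials$error_cm <- trials$endpoint_x_cm + trials$true_shift_cm - target_x

  present <- intersect(level_labels(), unique(trials$level))
  rows <- list()
  bins <- list()
  for (lv in present) {
    d <- trials[trials$level == lv, ]
    if (length(unique(d$true_shift_cm)) < 2L) {
      rows[[lv]] <- data.frame(level = lv, slope = NA_real_,
                               intercept_cm = NA_real_,
                               abscissa_crossing_cm = NA_real_,
                               n = nrow(d), degenerate = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    fit <- lm(error_cm ~ true_shift_cm, data = d)
    b <- coef(fit)
    slope <- unname(b[2])
    intercept <- unname(b[1])
    rows[[lv]] <- data.frame(
      level = lv, slope = slope, intercept_cm = intercept,
      abscissa_crossing_cm = if (slope != 0) -intercept / slope else NA_real_,
      n = nrow(d), degenerate = FALSE, stringsAsFactors = FALSE)
    breaks <- unique(quantile(d$true_shift_cm,
                              probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(breaks) > 1L) {
      grp <- cut(d$true_shift_cm, breaks = breaks, include.lowest = TRUE,
                 labels = FALSE)
      bins[[lv]] <- data.frame(
        level = lv, bin = sort(unique(grp)),
        shift_mean_cm = tapply(d$true_shift_cm, grp, mean),
        error_mean_cm = tapply(d$error_cm, grp, mean),
        n = as.integer(table(grp)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bins") <- do.call(rbind, bins)
  class(out) <- c("slope_fits", "data.frame")
  out
}

#' @export
print.slope_fits <- function(x, digits = 3, ...) {
  cat("Cursor-error slope fits (per uncertainty condition):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Percentage of interlimb generalization
#'
#' The ratio of mean early left-hand endpoints to mean late right-hand
#' endpoints, times 100. The headline figure is the magnitude (`percent`);
#' the raw signed ratio is retained since opposite-side endpoints make it
#' negative.
#'
#' @param early_lh,late_rh `"endpoint_summary"` objects (or bare means in
#'   cm). `late_rh` must have non-zero mean.
#' @return An object of class `"generalization_result"`: `percent`,
#'   `signed_percent`, `early_lh`, `late_rh`.
#' @examples
#' percent_generalization(0.31, -1.34)$percent    # ~23
#' percent_generalization(-0.60, -1.34)$percent   # ~45
#' @export
percent_generalization <- function(early_lh, late_rh) {
  early <- as_endpoint_summary(early_lh)
  late <- as_endpoint_summary(late_rh)
  if (late$mean_cm == 0) {
    stop("late right-hand mean endpoint is zero; generalization undefined",
         call. = FALSE)
  }
  signed <- 100 * early$mean_cm / late$mean_cm
  structure(list(percent = abs(signed), signed_percent = signed,
                 early_lh = early, late_rh = late),
            class = "generalization_result")
}

#' @export
print.generalization_result <- function(x, ...) {
  cat(sprintf("Generalization: %.1f%% (signed %.1f%%)\n", x$percent,
              x$signed_percent))
  cat(sprintf("  early LH: %.3f cm (n = %s); late RH: %.3f cm (n = %s)\n",
              x$early_lh$mean_cm, x$early_lh$n, x$late_rh$mean_cm,
              x$late_rh$n))
  invisible(x)
}

#' Interlimb generalization of a simulated or logged session
#'
#' Convenience wrapper applying the standard window conventions: late
#' right-hand training = trials 980--1080, early left-hand testing =
#' trials 1080--1180, no-feedback trials only.
#'
#' Sign convention: for a congruent-intrinsic (CI) session the testing-phase
#' perturbation is mirrored on screen, so early left-hand endpoints are
#' first expressed relative to the *testing-phase* perturbation direction
#' (sign-flipped) before the ratio. Under that convention `signed_percent`
#' is positive when transfer is appropriate to the testing limb's
#' perturbation and negative when the endpoint lands on the wrong side --
#' e.g. an extrinsically coded observer in a CI session scores about -100%.
#' For CE (and BSL) sessions the convention coincides with the raw ratio.
#' The unadjusted ratio is always available as `raw_signed_percent`.
#'
#' @param dataset A `"subject_dataset"`.
#' @param late_rh_range,early_lh_range Inclusive trial ranges.
#' @param congruence `"CE"`, `"CI"` or `"BSL"`; defaults to the dataset's
#'   group.
#' @return A `"generalization_result"` with additional fields
#'   `raw_signed_percent` and `congruence`.
#' @export
interlimb_generalization <- function(dataset,
                                     late_rh_range = c(980, 1080),
                                     early_lh_range = c(1080, 1180),
                                     congruence = NULL) {
  congruence <- congruence %||% dataset$group
  late <- mean_endpoint(sigma_inf_endpoints(dataset, late_rh_range))
  early <- mean_endpoint(sigma_inf_endpoints(dataset, early_lh_range))
  raw <- percent_generalization(early, late)
  out <- raw
  if (identical(congruence, "CI")) {
    adj <- early
    adj$mean_cm <- -adj$mean_cm
    out <- percent_generalization(adj, late)
    out$early_lh <- early   # report the unadjusted summary
  }
  out$raw_signed_percent <- raw$signed_percent
  out$congruence <- congruence
  out
}

#' Group-level generalization across subjects
#'
#' Two aggregation conventions, both reported: the ratio of group-mean
#' endpoints (`group_mean_percent`) and the mean of per-subject ratios
#' (`per_subject_percent`). The two differ slightly whenever subjects vary,
#' which is why both are exposed.
#'
#' @param datasets List of `"subject_dataset"` objects from one group.
#' @inheritParams interlimb_generalization
#' @return A list: `group_mean_percent`, `per_subject_percent`,
#'   `group_mean_signed`, `per_subject_signed`, and a per-subject data.frame
#'   `subjects`.
#' @export
group_generalization <- function(datasets, late_rh_range = c(980, 1080),
                                 early_lh_range = c(1080, 1180),
                                 congruence = NULL) {
  per <- lapply(datasets, interlimb_generalization,
                late_rh_range = late_rh_range,
                early_lh_range = early_lh_range, congruence = congruence)
  early_means <- vapply(per, function(g) g$early_lh$mean_cm, numeric(1))
  late_means <- vapply(per, function(g) g$late_rh$mean_cm, numeric(1))
  signed <- vapply(per, function(g) g$signed_percent, numeric(1))
  cong <- per[[1]]$congruence
  adj_early <- if (identical(cong, "CI")) -mean(early_means) else mean(early_means)
  gm_signed <- 100 * adj_early / mean(late_means)
  list(group_mean_percent = abs(gm_signed),
       per_subject_percent = mean(abs(signed)),
       group_mean_signed = gm_signed,
       per_subject_signed = mean(signed),
       subjects = data.frame(
         subject = seq_along(per), early_lh_cm = early_means,
         late_rh_cm = late_means, signed_percent = signed))
}

#' Moving-window endpoint series
#'
#' Consecutive non-overlapping windows over a trial range; each window is
#' summarized from the no-feedback trials it contains (mean, SD and count --
#' SDs are reported because the number of usable trials differs across
#' windows). The standard early-testing analysis uses 20 windows of 5 trials
#' over the first 100 left-hand trials.
#'
#' @param dataset A `"subject_dataset"` (or trial table).
#' @param start_trial First trial of the analysed range. Default 1080.
#' @param n_trials Number of trials covered. Default 100.
#' @param window_size Trials per window (>= 1). Default 5.
#' @return An object of class `"window_series"`: `window_size` and a
#'   data.frame `windows` (`window`, `from`, `to`, `n`, `mean_cm`, `sd_cm`).
#' @export
moving_window <- function(dataset, start_trial = 1080, n_trials = 100,
                          window_size = 5) {
  stopifnot(window_size >= 1, n_trials >= window_size)
  trials <- as_trials(dataset)
  n_windows <- n_trials %/% window_size
  rows <- lapply(seq_len(n_windows), function(w) {
    from <- start_trial + (w - 1L) * window_size
    to <- from + window_size - 1L
    sel <- trials$level == "INFINITE" & !trials$timeout &
      trials$index >= from & trials$index <= to
    ep <- trials$endpoint_x_cm[sel]
    ep <- ep[!is.na(ep)]
    data.frame(window = w, from = from, to = to, n = length(ep),
               mean_cm = if (length(ep)) mean(ep) else NA_real_,
               sd_cm = if (length(ep) > 1L) sd(ep) else NA_real_)
  })
  structure(list(window_size = window_size, windows = do.call(rbind, rows)),
            class = "window_series")
}

#' @export
print.window_series <- function(x, digits = 3, ...) {
  cat(sprintf("Moving-window endpoint series (window = %d trials):\n",
              x$window_size))
  print.data.frame(x$windows, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Representativeness of condition sampling within windows
#'
#' Checks whether each analysis window samples the uncertainty conditions in
#' proportions representative of the scheduled ratio: per-window condition
#' counts plus the aggregate relative frequencies and their deviation from
#' the expected ratio.
#'
#' @param design An `"experiment_design"` (or trial table).
#' @param start_trial,n_trials,window_size As in [moving_window()].
#' @param ratio Expected condition ratio; defaults to the design's own.
#' @return A list: `per_window` (counts per condition per window),
#'   `aggregate` (observed relative frequency per condition), `expected`
#'   (ratio normalized), `max_abs_deviation`.
#' @export
window_representativeness <- function(design, start_trial = 1080,
                                      n_trials = 100, window_size = 5,
                                      ratio = NULL) {
  trials <- as_trials(design)
  if (is.null(ratio)) {
    ratio <- if (inherits(design, "experiment_design") &&
                 !is.null(design$ratio)) design$ratio else c(3, 1, 1, 1)
  }
  n_windows <- n_trials %/% window_size
  labels <- level_labels()
  counts <- t(vapply(seq_len(n_windows), function(w) {
    from <- start_trial + (w - 1L) * window_size
    to <- from + window_size - 1L
    lv <- trials$level[trials$index >= from & trials$index <= to]
    vapply(labels, function(l) sum(lv == l), numeric(1))
  }, numeric(length(labels))))
  per_window <- data.frame(window = seq_len(n_windows), counts)
  names(per_window) <- c("window", labels)
  agg <- colSums(counts)
  observed <- agg / sum(agg)
  expected <- setNames(ratio / sum(ratio), labels)
  list(per_window = per_window,
       aggregate = setNames(observed, labels),
       expected = expected,
       max_abs_deviation = max(abs(observed - expected)))
}
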