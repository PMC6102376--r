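#' The Gaussian prior over lateral cursor shifts
#'
#' On every trial of the task the visual cursor is displaced laterally from
#' the true hand position by an amount drawn from a fixed Gaussian
#' distribution. Learning the parameters of that distribution -- the prior --
#' is what the paradigm probes. The standard task prior has mean 1 cm
#' (rightward on screen) and SD 0.5 cm.
#'
#' @param mean_cm Mean lateral shift in cm; positive values are rightward in
#'   screen coordinates.
#' @param sd_cm Standard deviation of the shift distribution in cm (> 0).
#' @return An object of class `"shift_prior"` with fields `mean_cm`, `sd_cm`.
#' @examples
#' shift_prior()          # the standard task prior
#' shift_prior(0, 0.25)   # a custom, zero-mean prior
#' @export
shift_prior <- function(mean_cm = 1, sd_cm = 0.5) {
  stopifnot(is.numeric(mean_cm), length(mean_cm) == 1L, is.finite(mean_cm),
            is.numeric(sd_cm), length(sd_cm) == 1L, is.finite(sd_cm))
  if (sd_cm <= 0) stop("`sd_cm` must be > 0", call. = FALSE)
  structure(list(mean_cm = mean_cm, sd_cm = sd_cm), class = "shift_prior")
}

#' @export
print.shift_prior <- function(x, ...) {
  cat(sprintf("Shift prior: Gaussian(mean = %g cm, SD = %g cm)\n",
              x$mean_cm, x$sd_cm))
  invisible(x)
}

#' Midpoint-feedback uncertainty conditions
#'
#' Definition table for the four visual uncertainty conditions. `ZERO` shows
#' a single clear sphere at the (displaced) cursor position at the reach
#' midpoint and is the only condition with endpoint feedback; `MODERATE` and
#' `LARGE` show translucent point clouds (2-D Gaussian, SD 1 and 2 cm) centred
#' on the displaced cursor; `INFINITE` provides no midpoint feedback at all.
#' Midpoint feedback, when shown, lasts 100 ms.
#'
#' @param n_spheres_cloud Number of spheres per point cloud. Default 50.
#' @return A data.frame with one row per condition label and columns
#'   `label`, `cloud_sd_cm`, `n_spheres`, `sphere_diameter_cm`,
#'   `midpoint_feedback`, `endpoint_feedback`, `feedback_duration_ms`.
#' @examples
#' uncertainty_levels()
#' @export
uncertainty_levels <- function(n_spheres_cloud = 50L) {
  stopifnot(is.numeric(n_spheres_cloud), n_spheres_cloud >= 1)
  data.frame(
    label = level_labels(),
    cloud_sd_cm = c(0, 1, 2, NA_real_),
    n_spheres = c(1L, as.integer(n_spheres_cloud), as.integer(n_spheres_cloud), 0L),
    sphere_diameter_cm = c(1, 0.2, 0.2, NA_real_),
    midpoint_feedback = c(TRUE, TRUE, TRUE, FALSE),
    endpoint_feedback = c(TRUE, FALSE, FALSE, FALSE),
    feedback_duration_ms = c(100, 100, 100, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Build a trial-by-trial schedule of uncertainty conditions
#'
#' Produces the ordered sequence of uncertainty-condition labels for a
#' session. In the default `"block_exact"` mode every block of
#' `block_size` trials contains the conditions in exactly the requested
#' ratio (the standard 1080-trial block holds 540 ZERO, 180 MODERATE,
#' 180 LARGE and 180 INFINITE trials), with a seeded uniform shuffle within
#' each block. An `"iid"` mode that samples each trial independently with
#' the ratio as probabilities is available as well.
#'
#' @param n_trials Total number of trials; in `"block_exact"` mode it must be
#'   a whole multiple of `block_size`.
#' @param ratio Integer ratio of the four conditions, in the order of
#'   [uncertainty_levels()]. Default `c(3, 1, 1, 1)`.
#' @param block_size Trials per block. Default 1080. Must be divisible by
#'   `sum(ratio)`.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   schedule.
#' @param mode `"block_exact"` (default) or `"iid"`.
#' @return Character vector of length `n_trials` of condition labels.
#' @examples
#' s <- build_condition_schedule(1080, seed = 1)
#' table(s)   # exactly 540/180/180/180
#' @export
build_condition_schedule <- function(n_trials, ratio = c(3, 1, 1, 1),
                                     block_size = 1080, seed = NULL,
                                     mode = c("block_exact", "iid")) {
  mode <- match.arg(mode)
  labels <- level_labels()
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 0)
  if (length(ratio) != length(labels) || any(ratio <= 0)) {
    stop("`ratio` must give a positive count for each of the ",
         length(labels), " conditions", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (mode == "iid") {
    return(with_seed_if(seed,
      sample(labels, n_trials, replace = TRUE, prob = ratio / sum(ratio))))
  }
  if (block_size %% sum(ratio) != 0) {
    stop(sprintf("`block_size` (%d) must be divisible by sum(ratio) (%d)",
                 as.integer(block_size), as.integer(sum(ratio))),
         call. = FALSE)
  }
  if (n_trials %% block_size != 0) {
    stop(sprintf("`n_trials` (%d) must be a whole multiple of `block_size` (%d)",
                 n_trials, as.integer(block_size)), call. = FALSE)
  }
  counts <- block_size / sum(ratio) * ratio
  n_blocks <- n_trials %/% block_size
  with_seed_if(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(labels, times = counts))
    }), use.names = FALSE) %||% character(0)
  })
}

#' Draw lateral cursor shifts from the prior
#'
#' i.i.d. Gaussian draws with no truncation: occasional leftward (negative)
#' shifts occur with probability `pnorm(-mean/sd)` (about 2.3% for the
#' standard prior).
#'
#' @param prior A [shift_prior()].
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of signed shifts in cm.
#' @examples
#' mean(sample_shifts(shift_prior(), 1e4, seed = 1))
#' @export
sample_shifts <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "shift_prior"), is.numeric(n), n >= 0)
  with_seed_if(seed, rnorm(as.integer(n), prior$mean_cm, prior$sd_cm))
}

#' Construct a full experiment design
#'
#' Builds the complete trial table for one of the three session designs:
#' \describe{
#'   \item{BSL}{2160 right-hand trials; trials 1--1080 are nominally the
#'     training phase and 1081--2160 the testing phase.}
#'   \item{CE}{1080 right-hand training trials followed by 1080 left-hand
#'     testing trials whose shifts are drawn from the same prior
#'     (congruent in extrinsic, screen-based coordinates).}
#'   \item{CI}{As CE, but the left-hand shifts are the sign-negated draws
#'     (mean -1 cm for the standard prior; congruent in intrinsic,
#'     joint-based coordinates).}
#' }
#' For matched seeds the CE and CI designs use identical underlying draws, so
#' the CI left-hand shifts mirror the CE ones trial by trial.
#'
#' @param name `"BSL"`, `"CE"` or `"CI"`.
#' @param seed Optional integer seed.
#' @param prior The shift prior, default [shift_prior()].
#' @param block_size,ratio Passed to [build_condition_schedule()].
#' @return An object of class `"experiment_design"` with fields `name`,
#'   `trials` (data.frame: `index`, `phase`, `hand`, `level`,
#'   `true_shift_cm`), `block_size`, `ratio` and `prior`.
#' @examples
#' d <- make_design("CE", seed = 1)
#' table(d$trials$hand, d$trials$phase)
#' @export
make_design <- function(name = c("BSL", "CE", "CI"), seed = NULL,
                        prior = shift_prior(), block_size = 1080,
                        ratio = c(3, 1, 1, 1)) {
  name <- match.arg(name)
  n_total <- 2L * as.integer(block_size)
  trials <- with_seed_if(seed, {
    if (name == "BSL") {
      lev <- build_condition_schedule(n_total, ratio, block_size)
      sh <- sample_shifts(prior, n_total)
      hand <- rep("RH", n_total)
    } else {
      lev <- c(build_condition_schedule(block_size, ratio, block_size),
               build_condition_schedule(block_size, ratio, block_size))
      sh_train <- sample_shifts(prior, block_size)
      sh_test <- sample_shifts(prior, block_size)
      if (name == "CI") sh_test <- -sh_test
      sh <- c(sh_train, sh_test)
      hand <- rep(c("RH", "LH"), each = block_size)
    }
    data.frame(
      index = seq_len(n_total),
      phase = rep(c("training", "testing"), each = block_size),
      hand = hand,
      level = lev,
      true_shift_cm = sh,
      stringsAsFactors = FALSE
    )
  })
  structure(list(name = name, trials = trials,
                 block_size = as.integer(block_size), ratio = ratio,
                 prior = prior),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design %s: %d trials (%s)\n", x$name,
              nrow(x$trials),
              paste(sprintf("%s x %d", names(table(x$trials$hand)),
                            as.integer(table(x$trials$hand))),
                    collapse = ", ")))
  print(table(x$trials$level)[level_labels()])
  invisible(x)
}

#' Single-condition probe design
#'
#' A minimal design in which every trial uses the same hand and the same
#' uncertainty condition, with shifts drawn from the prior. Useful for
#' model probes (e.g. a long run of no-feedback trials to read out the
#' learned prior, or a run of MODERATE trials for slope fits).
#'
#' @param n_trials Number of trials.
#' @param level Condition label for every trial.
#' @param hand `"RH"` or `"LH"`.
#' @param phase Phase label recorded for every trial.
#' @param prior,seed As in [make_design()].
#' @return An `"experiment_design"` whose `name` is `"PROBE"`.
#' @export
single_level_design <- function(n_trials, level = "INFINITE", hand = "RH",
                                phase = "testing", prior = shift_prior(),
                                seed = NULL) {
  check_level(level)
  check_hand(hand)
  n_trials <- as.integer(n_trials)
  trials <- data.frame(
    index = seq_len(n_trials),
    phase = rep(phase, n_trials),
    hand = rep(hand, n_trials),
    level = rep(level, n_trials),
    true_shift_cm = sample_shifts(prior, n_trials, seed = seed),
    stringsAsFactors = FALSE
  )
  structure(list(name = "PROBE", trials = trials, block_size = NA_integer_,
                 ratio = NULL, prior = prior),
            class = "experiment_design")
}

#' Generate sphere positions for a midpoint-feedback stimulus
#'
#' Coordinates only; rendering is out of scope. `ZERO` yields the single
#' (displaced) cursor position, `MODERATE` and `LARGE` yield an isotropic
#' 2-D Gaussian cloud of spheres centred on it with the condition's cloud SD,
#' and `INFINITE` yields no spheres.
#'
#' @param center_xy Numeric length-2, the displaced cursor position (cm).
#' @param level Condition label.
#' @param seed Optional integer seed.
#' @param levels Condition table, default [uncertainty_levels()].
#' @return data.frame with columns `x_cm`, `y_cm` (0 rows for `INFINITE`).
#' @export
render_point_cloud <- function(center_xy, level, seed = NULL,
                               levels = uncertainty_levels()) {
  check_level(level)
  stopifnot(is.numeric(center_xy), length(center_xy) == 2L)
  row <- levels[levels$label == level, ]
  if (!row$midpoint_feedback || row$n_spheres == 0L) {
    return(data.frame(x_cm = numeric(0), y_cm = numeric(0)))
  }
  if (row$cloud_sd_cm == 0) {
    return(data.frame(x_cm = center_xy[1], y_cm = center_xy[2]))
  }
  with_seed_if(seed, data.frame(
    x_cm = rnorm(row$n_spheres, center_xy[1], row$cloud_sd_cm),
    y_cm = rnorm(row$n_spheres, center_xy[2], row$cloud_sd_cm)
  ))
}

design_columns <- c("index", "phase", "hand", "level", "true_shift_cm")

#' Write or read a design trial table
#'
#' Tab-delimited UTF-8 table, one row per trial, header row required,
#' columns `index`, `phase`, `hand`, `level`, `true_shift_cm`.
#'
#' @param design An `"experiment_design"`.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns an `"experiment_design"` (with `prior` unknown, set to NULL).
#' @export
write_design <- function(design, path) {
  trials <- as_trials(design)
  write.table(trials[, design_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @param name Design name to record on the object read back.
#' @export
read_design <- function(path, name = "BSL") {
  trials <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(design_columns, names(trials))
  if (length(missing)) {
    stop("design file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(trials$index != seq_len(nrow(trials)))) {
    stop("trial `index` must be contiguous starting at 1", call. = FALSE)
  }
  structure(list(name = name, trials = trials, block_size = NA_integer_,
                 ratio = NULL, prior = NULL),
            class = "experiment_design")
}
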