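# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed when one is supplied, leaving the
# caller's RNG stream untouched; with seed = NULL the ambient stream is used.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The four midpoint-feedback uncertainty conditions, in canonical order.
level_labels <- function() c("ZERO", "MODERATE", "LARGE", "INFINITE")

check_level <- function(level) {
  if (length(level) != 1L || !level %in% level_labels()) {
    stop("`level` must be one of ", paste(level_labels(), collapse = ", "),
         call. = FALSE)
  }
  level
}

check_hand <- function(hand) {
  if (!all(hand %in% c("RH", "LH"))) {
    stop("`hand` must be \"RH\" or \"LH\"", call. = FALSE)
  }
  hand
}

# Accept either a subject dataset, an experiment design, or a bare trial
# table, and return the trial-level data.frame.
as_trials <- function(x) {
  if (inherits(x, "subject_dataset")) return(x$trials)
  if (inherits(x, "experiment_design")) return(x$trials)
  if (is.data.frame(x)) return(x)
  stop("expected a subject_dataset, experiment_design, or trial data.frame",
       call. = FALSE)
}
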