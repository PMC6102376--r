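make_toy_dataset <- function(n = 60, seed = 1) {
  d <- make_design("BSL", seed = seed)
  generate_subject(d$trials[seq_len(n), ], converged("BAYES"), seed = seed + 1)
}

test_that("no-feedback endpoint selection matches a brute-force filter", {
  s <- make_toy_dataset(300, seed = 2)
  got <- sigma_inf_endpoints(s, c(50, 250))
  tr <- s$trials
  want <- tr$endpoint_x_cm[tr$level == "INFINITE" & !tr$timeout &
                             tr$index >= 50 & tr$index <= 250]
  expect_identical(got, want)

  # inclusive 1-based bounds: the 980-1080 convention selects 101 trials
  d <- make_design("BSL", seed = 3)
  sub <- d$trials[d$trials$index >= 980 & d$trials$index <= 1080, ]
  expect_equal(nrow(sub), 101)

  # a range with no no-feedback trials is explicitly empty
  one <- s$trials[s$trials$level != "INFINITE", ]$index[1]
  expect_length(sigma_inf_endpoints(s, c(one, one)), 0)
  expect_error(mean_endpoint(numeric(0)), "empty")
  expect_error(sigma_inf_endpoints(s, c(0, 10)), "within")
})

test_that("endpoint summaries compute mean and sample SD", {
  s <- mean_endpoint(c(-1, -1, -1))
  expect_equal(s$mean_cm, -1)
  expect_equal(s$sd_cm, 0)
  s2 <- mean_endpoint(c(-2, 0))
  expect_equal(s2$mean_cm, -1)
  expect_equal(s2$sd_cm, sqrt(2))
  expect_equal(s2$n, 2)
})

test_that("baseline correction subtracts the baseline mean", {
  expect_equal(baseline_correct(c(1, 2), 0), c(1, 2))
  expect_equal(baseline_correct(-1.51, -0.35), -1.16)
  expect_equal(baseline_correct(-1.51, mean_endpoint(c(-0.35, -0.35))),
               -1.16)
})

test_that("cursor-error slopes recover each model's signature", {
  n <- 2160
  # full compensation with noiseless sensing: flat error line
  d <- single_level_design(500, "ZERO", seed = 4)
  pfc <- converged("FULL_COMP", motor_noise_sd_cm = 0,
                   sigma_s_by_level = c(ZERO = 0, MODERATE = 1, LARGE = 2,
                                        INFINITE = NA))
  sfc <- generate_subject(d, pfc, seed = 5)
  fit <- cursor_error_slopes(sfc, c(1, 500))
  expect_equal(fit$slope[fit$level == "ZERO"], 0, tolerance = 0.03)

  # minimal mapping: unit slope crossing the abscissa at the prior mean
  dmm <- make_design("BSL", seed = 6)
  smm <- generate_subject(dmm, converged("MINIMAL_MAP"), seed = 7)
  fmm <- cursor_error_slopes(smm, c(1, n))
  expect_equal(fmm$slope, rep(1, 4), tolerance = 0.08)
  expect_equal(fmm$abscissa_crossing_cm, rep(1, 4), tolerance = 0.1)

  # Bayes at sigma_s = sigma_p: slope one half
  db <- single_level_design(n, "MODERATE", seed = 8)
  pb <- converged("BAYES", sigma_p_cm = 1)
  sb <- generate_subject(db, pb, seed = 9)
  fb <- cursor_error_slopes(sb, c(1, n))
  expect_equal(fb$slope[fb$level == "MODERATE"], 0.5, tolerance = 0.06)
})

test_that("slope fits flag degenerate conditions and expose display bins", {
  tr <- data.frame(index = 1:10, phase = "testing", hand = "RH",
                   level = "ZERO", true_shift_cm = 1,
                   endpoint_x_cm = rnorm(10), endpoint_y_cm = 20,
                   timeout = FALSE)
  fit <- cursor_error_slopes(tr, c(1, 10))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$slope))

  s <- make_toy_dataset(300, seed = 10)
  fit2 <- cursor_error_slopes(s, c(1, 300))
  bins <- attr(fit2, "bins")
  expect_true(all(table(bins$level) <= 11))
  # bin means of the largest condition average to the trial-level mean
  z <- s$trials[s$trials$level == "ZERO" & !s$trials$timeout, ]
  zb <- bins[bins$level == "ZERO", ]
  expect_equal(sum(zb$shift_mean_cm * zb$n) / sum(zb$n),
               mean(z$true_shift_cm))
})

test_that("the generalization ratio reproduces the worked group numbers", {
  g <- percent_generalization(0.31, -1.34)
  expect_equal(round(g$percent), 23)
  expect_equal(g$signed_percent, 100 * 0.31 / -1.34)

  g2 <- percent_generalization(-0.60, -1.34)
  expect_equal(round(g2$percent), 45)

  full <- percent_generalization(-1.2, -1.2)
  expect_equal(full$percent, 100)
  expect_equal(full$signed_percent, 100)

  expect_error(percent_generalization(0.5, 0), "zero")
})

test_that("design-aware generalization applies the congruence convention", {
  # hand-built logs: late RH at -1, early LH at -1 (extrinsic-style transfer)
  mk <- function(group, lh_mean) {
    idx <- 1:2160
    lev <- rep("INFINITE", 2160)
    hand <- rep(c("RH", "LH"), each = 1080)
    ep <- c(rep(-1, 1080), rep(lh_mean, 1080))
    structure(list(subject_id = "T", group = group,
                   baseline_bias_cm = c(RH = 0, LH = 0),
                   trials = data.frame(subject_id = "T", group = group,
                                       index = idx, phase = "x", hand = hand,
                                       level = lev, true_shift_cm = 1,
                                       endpoint_x_cm = ep,
                                       endpoint_y_cm = 20, timeout = FALSE),
                   trajectories = NULL, final_state = NULL),
              class = "subject_dataset")
  }
  ce <- interlimb_generalization(mk("CE", -1))
  expect_equal(ce$signed_percent, 100)
  # same endpoints under CI scoring: the wrong side for the mirrored shift
  ci <- interlimb_generalization(mk("CI", -1))
  expect_equal(ci$signed_percent, -100)
  expect_equal(ci$raw_signed_percent, 100)
  # intrinsic-style transfer in a CI session scores fully positive; the
  # inclusive 1080-1180 window contains one final RH trial, hence 99/101
  ci2 <- interlimb_generalization(mk("CI", 1))
  expect_equal(ci2$signed_percent, 100 * 99 / 101)
})

test_that("moving windows tile the range and match brute-force recomputation", {
  s <- make_toy_dataset(300, seed = 11)
  ws <- moving_window(s, start_trial = 101, n_trials = 100, window_size = 5)
  expect_equal(nrow(ws$windows), 20)
  expect_equal(ws$windows$from[1], 101)
  expect_equal(ws$windows$to[20], 200)

  tr <- s$trials
  for (w in c(1, 7, 20)) {
    from <- 101 + (w - 1) * 5
    keep <- tr$level == "INFINITE" & !tr$timeout & tr$index >= from &
      tr$index <= from + 4
    if (any(keep)) {
      expect_equal(ws$windows$mean_cm[w], mean(tr$endpoint_x_cm[keep]))
      expect_equal(ws$windows$n[w], sum(keep))
    } else {
      expect_true(is.na(ws$windows$mean_cm[w]))
    }
  }

  # constant endpoints give constant window means
  s$trials$endpoint_x_cm <- -1
  wc <- moving_window(s, 1, 300, 5)
  expect_true(all(is.na(wc$windows$mean_cm) | wc$windows$mean_cm == -1))
})

test_that("window representativeness recovers the scheduled ratio", {
  d <- make_design("BSL", seed = 12)
  # one window spanning a whole block reproduces the ratio exactly
  whole <- window_representativeness(d, start_trial = 1, n_trials = 1080,
                                     window_size = 1080)
  expect_equal(unname(whole$aggregate),
               c(3, 1, 1, 1) / 6, tolerance = 1e-12)
  expect_equal(whole$max_abs_deviation, 0)

  # per-window counts equal a direct tally
  rep5 <- window_representativeness(d, start_trial = 1080, n_trials = 100,
                                    window_size = 5)
  expect_equal(nrow(rep5$per_window), 20)
  lv <- d$trials$level[d$trials$index >= 1080 & d$trials$index <= 1084]
  expect_equal(unname(unlist(rep5$per_window[1, -1])),
               c(sum(lv == "ZERO"), sum(lv == "MODERATE"),
                 sum(lv == "LARGE"), sum(lv == "INFINITE")))
  expect_equal(sum(rep5$per_window[, -1]), 100)
})

test_that("group-level generalization offers both aggregation conventions", {
  sims <- lapply(1:3, function(i) {
    d <- make_design("CE", seed = 20 + i)
    generate_subject(d, converged("BAYES"), seed = 30 + i)
  })
  g <- group_generalization(sims)
  expect_equal(g$group_mean_signed, 100, tolerance = 20)
  expect_equal(g$per_subject_signed, 100, tolerance = 20)
  expect_equal(nrow(g$subjects), 3)
})
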