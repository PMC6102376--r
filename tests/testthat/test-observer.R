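test_that("sensing adds condition-specific noise and respects absent feedback", {
  p <- observer_params("BAYES",
                       sigma_s_by_level = c(ZERO = 0, MODERATE = 1, LARGE = 2,
                                            INFINITE = NA))
  expect_equal(sense_shift(2, "ZERO", p)$value_cm, 2)
  expect_true(is.na(sense_shift(2, "INFINITE", p)$value_cm))

  vals <- withr::with_seed(1, replicate(1e4, {
    sense_shift(2, "MODERATE", p)$value_cm
  }))
  expect_equal(mean(vals), 2, tolerance = 0.05)
  expect_equal(sd(vals), 1, tolerance = 0.05)
})

test_that("the reliability-weighted estimate obeys its limits", {
  expect_equal(bayes_estimate(NA, 1, 0.5, NA), 1)
  expect_equal(bayes_estimate(2, 1, 1, 1), 1.5)
  expect_equal(bayes_estimate(2, 1, 0.5, 0), 2)
  expect_equal(bayes_estimate(2, 1, 0.5, Inf), 1)
  expect_error(bayes_estimate(2, 1, 0, 0), "undefined weighting")
})

test_that("the two reliability weights always sum to one", {
  set.seed(3)
  for (i in 1:50) {
    sp <- runif(1, 0.05, 3)
    ss <- runif(1, 0, 3)
    prior <- runif(1, -2, 2)
    sensed <- runif(1, -3, 3)
    est <- bayes_estimate(sensed, prior, sp, ss)
    ws <- ss^2 / (ss^2 + sp^2)
    expect_equal(est, ws * prior + (1 - ws) * sensed, tolerance = 1e-12)
    # equivalently: the estimate is a convex combination
    expect_true(est >= min(prior, sensed) - 1e-12 &&
                est <= max(prior, sensed) + 1e-12)
  }
})

test_that("posterior variance is the product over the sum and bounded above", {
  expect_equal(posterior_variance(1, 1), 0.5)
  expect_equal(posterior_variance(Inf, 0.7), 0.49)
  expect_equal(posterior_variance(2, 0.5), 4 * 0.25 / 4.25)
  set.seed(4)
  for (i in 1:25) {
    ss <- runif(1, 0.01, 3); sp <- runif(1, 0.01, 3)
    expect_lte(posterior_variance(ss, sp), min(ss^2, sp^2))
  }
  expect_error(posterior_variance(0, 0), "positive")
})

test_that("predicted error slope spans [0, 1] and rises with sensory noise", {
  expect_equal(predicted_error_slope(0, 0.5), 0)
  expect_equal(predicted_error_slope(NA, 0.5), 1)
  expect_equal(predicted_error_slope(1, 1), 0.5)
  grid <- seq(0, 5, by = 0.1)
  slopes <- predicted_error_slope(grid, 0.5)
  expect_true(all(diff(slopes) > 0))
  expect_true(all(slopes >= 0 & slopes <= 1))
})

test_that("the three models plan the compensation the task theory predicts", {
  p <- converged("BAYES", sigma_s_by_level = c(ZERO = 0.5, MODERATE = 0.5,
                                               LARGE = 2, INFINITE = NA))
  st <- initial_state(p)
  sensed2 <- structure(list(value_cm = 2, level = "MODERATE"),
                       class = "sensed_shift")
  absent <- structure(list(value_cm = NA_real_, level = "INFINITE"),
                      class = "sensed_shift")

  expect_equal(plan_compensation("FULL_COMP", sensed2, st, p), -2)
  expect_equal(plan_compensation("FULL_COMP", absent, st, p), -1)
  expect_equal(plan_compensation("MINIMAL_MAP", sensed2, st, p), -1)
  expect_equal(plan_compensation("MINIMAL_MAP", absent, st, p), -1)
  # sigma_s = sigma_p: midpoint between prior and evidence
  expect_equal(plan_compensation("BAYES", sensed2, st, p), -1.5)
  expect_error(plan_compensation("RANDOM", sensed2, st, p), "unknown")
})

test_that("Bayes reduces to full compensation and minimal mapping in the limits", {
  p0 <- converged("BAYES", sigma_s_by_level = c(ZERO = 0, MODERATE = 1,
                                                LARGE = 2, INFINITE = NA))
  st <- initial_state(p0)
  for (x in c(-1, 0.3, 2.5)) {
    s <- structure(list(value_cm = x, level = "ZERO"), class = "sensed_shift")
    expect_equal(plan_compensation("BAYES", s, st, p0),
                 plan_compensation("FULL_COMP", s, st, p0))
  }
  absent <- structure(list(value_cm = NA_real_, level = "INFINITE"),
                      class = "sensed_shift")
  expect_equal(plan_compensation("BAYES", absent, st, p0),
               plan_compensation("MINIMAL_MAP", absent, st, p0))
})

test_that("the prior-mean estimate converges and its uncertainty never grows", {
  st <- observer_state(0, 5)
  obs <- sample_shifts(shift_prior(), 1000, seed = 11)
  unc <- numeric(1000)
  for (i in seq_along(obs)) {
    st <- update_prior_estimate(st, obs[i], 0.1)
    unc[i] <- st$prior_uncertainty_cm
  }
  expect_equal(st$prior_mean_estimate_cm, 1, tolerance = 0.1)
  expect_true(all(diff(unc) <= 1e-12))

  # absent observation leaves the state untouched
  st2 <- update_prior_estimate(st, NA, 0.1)
  expect_identical(st2, st)
})

test_that("frame encoding flips only left-hand values in intrinsic coding", {
  expect_equal(encode_in_frame(1, "RH", "INTRINSIC"), 1)
  expect_equal(encode_in_frame(1, "LH", "INTRINSIC"), -1)
  expect_equal(encode_in_frame(1, "LH", "EXTRINSIC"), 1)
  # involution: encoding twice is the identity
  set.seed(5)
  v <- rnorm(20)
  hands <- sample(c("RH", "LH"), 20, replace = TRUE)
  for (fr in c("EXTRINSIC", "INTRINSIC")) {
    expect_equal(encode_in_frame(encode_in_frame(v, hands, fr), hands, fr), v)
  }
  expect_error(encode_in_frame(1, "XX", "EXTRINSIC"), "hand")
})

test_that("observer parameter validation catches inconsistent noise maps", {
  expect_error(observer_params("BAYES",
                               sigma_s_by_level = c(ZERO = 0.1, MODERATE = 1,
                                                    LARGE = 2, INFINITE = 1)),
               "INFINITE")
  expect_error(observer_params("BAYES",
                               sigma_s_by_level = c(ZERO = 0.1, MODERATE = 1)),
               "missing")
  expect_error(observer_params("BAYES", sigma_p_cm = 0), "sigma_p_cm")
})
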