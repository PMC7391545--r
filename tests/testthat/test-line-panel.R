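test_that("degenerate failure probabilities give the trivial trajectories", {
  all_live <- simulate_line_panel(50, 10, 3, failure_prob = 0, seed = 1)
  expect_identical(all_live$survivors, rep(50L, 11))
  all_dead <- simulate_line_panel(50, 10, 3, failure_prob = 1, seed = 1)
  expect_identical(all_dead$survivors, c(50L, rep(0L, 10)))
})

test_that("panel trajectories are non-increasing, seeded and replicate-buffered", {
  p <- simulate_line_panel(200, 15, 3, failure_prob = 0.5, seed = 8)
  expect_true(all(diff(p$survivors) <= 0))
  expect_identical(p$survivors[1], 200L)
  p2 <- simulate_line_panel(200, 15, 3, failure_prob = 0.5, seed = 8)
  expect_identical(p$survivors, p2$survivors)
  # more replicates per line buffer more losses (paired by expectation)
  set.seed(21)
  one_rep <- replicate_line_panels(400, 200, 15, 1, failure_prob = 0.5)
  set.seed(21)
  three_rep <- replicate_line_panels(400, 200, 15, 3, failure_prob = 0.5)
  expect_gt(three_rep$mean_final, one_rep$mean_final)
})

test_that("failure causes are attributed without altering survival dynamics", {
  causes <- c(female_death = 0.2, null_fecundity = 0.1,
              no_hatching = 0.1, single_sex_brood = 0.1)
  p <- simulate_line_panel(100, 10, 3, failure_prob = 0.5,
                           cause_probs = causes, seed = 4)
  expect_identical(names(p$cause_counts), names(causes))
  expect_true(sum(p$cause_counts) > 0)
  expect_error(simulate_line_panel(100, 10, 3, failure_prob = 0.5,
                                   cause_probs = c(a = 0.1), seed = 4),
               "sum to")
})

test_that("failure probability calibrates by inverting expected survival", {
  expect_identical(calibrate_failure_prob(450, 450, 15, 3), 0)
  q <- calibrate_failure_prob(450, 59, 15, 3)
  expect_equal(q, 0.502, tolerance = 1e-3)
  # the calibrated value reproduces the endpoint in expectation
  expect_equal(450 * (1 - q^3)^15, 59, tolerance = 1e-6)
  expect_error(calibrate_failure_prob(450, 500, 15, 3), "exceed")
  expect_error(calibrate_failure_prob(450, 0, 15, 3), "unattainable")
})

test_that("replicated panels under the calibrated rate centre on the observed endpoint", {
  q <- calibrate_failure_prob(450, 59, 15, 3)
  mc <- replicate_line_panels(2000, 450, 15, 3, failure_prob = q, seed = 2)
  expect_lt(abs(mc$mean_final - 59), 3 * mc$se_final)
  expect_true(all(diff(mc$mean_trajectory) <= 0))
})
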