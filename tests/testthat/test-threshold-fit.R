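test_that("binning aggregates hit rates over half-open dose bins", {
  tr <- data.frame(intensity_value = c(0.6, 0.7, 0.9),
                   outcome = c("hit", "hit", "miss"))
  pts <- bin_responses(tr, 0.5)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$dose, 0.75)
  expect_equal(pts$hit_rate_percent, 100 * 2 / 3)
  expect_equal(pts$n_trials, 3L)

  one <- bin_responses(data.frame(intensity_value = 0.2, outcome = "miss"), 0.5)
  expect_equal(one$dose, 0.25)
  expect_equal(one$hit_rate_percent, 0)

  allhit <- bin_responses(data.frame(intensity_value = c(0.2, 0.8, 1.9),
                                     outcome = "hit"), 0.5)
  expect_true(all(allhit$hit_rate_percent == 100))

  # bin boundary: 0.5 belongs to [0.5, 1.0)
  bd <- bin_responses(data.frame(intensity_value = c(0.499, 0.5),
                                 outcome = c("hit", "hit")), 0.5)
  expect_equal(bd$dose, c(0.25, 0.75))

  expect_error(bin_responses(data.frame(intensity_value = numeric(0),
                                        outcome = character(0)), 0.5),
               "no dynamic trials")
})

test_that("binning keeps only non-distracted dynamic trials", {
  tr <- data.frame(
    trial_type = c("dynamic", "dynamic", "naive_anchor", "catch", "dynamic"),
    intensity_value = c(0.6, 0.8, 3, NA, 0.7),
    outcome = c("hit", "miss", "hit", "correct_rejection", "hit"),
    distracted = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  pts <- bin_responses(tr, 0.5)
  expect_equal(pts$n_trials, 2L)  # the anchor, catch and distracted rows drop
  expect_equal(pts$hit_rate_percent, 50)
})

test_that("noiseless Hill data are recovered to high precision", {
  pts <- hill_points(c(0.25, 0.75, 1.25, 1.75, 2.25, 2.75), ed50 = 1.5, slope = 2)
  fit <- fit_quantal(pts)
  expect_equal(unname(fit$ed50), 1.5, tolerance = 1e-6)
  expect_equal(fit$hillslope, 2, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  # the fitted curve passes 50% at its ED50 (definition of ED50)
  expect_equal(unname(hill_response(fit$ed50, fit$ed50, fit$hillslope)), 50)
})

test_that("the fitted curve is anchored at 0% and saturates at 100%", {
  expect_equal(hill_response(0, 1.5, 2), 0)
  expect_equal(hill_response(1e9, 1.5, 2), 100, tolerance = 1e-6)
})

test_that("the shared slope is estimated jointly across sessions", {
  doses <- c(0.25, 0.75, 1.25, 1.75, 2.25)
  pts <- list(hill_points(doses, ed50 = 1.2, slope = 3),
              hill_points(doses, ed50 = 1.8, slope = 3))
  fit <- fit_quantal(pts)
  expect_equal(unname(fit$ed50), c(1.2, 1.8), tolerance = 1e-5)
  expect_equal(fit$hillslope, 3, tolerance = 1e-5)
  expect_equal(fit$threshold_mean, 1.5, tolerance = 1e-5)
  expect_equal(fit$threshold_se, sd(c(1.2, 1.8)) / sqrt(2), tolerance = 1e-5)
})

test_that("fit matches an independent grid-search minimizer on noisy data", {
  set.seed(9)
  doses <- c(0.25, 0.75, 1.25, 1.75, 2.25, 2.75)
  mk <- function(ed50) {
    p <- hill_points(doses, ed50, slope = 2.5)
    p$hit_rate_percent <- pmin(100, pmax(0, p$hit_rate_percent + rnorm(6, 0, 8)))
    p
  }
  pts <- list(mk(1.3), mk(1.7))
  fit <- fit_quantal(pts)
  oracle <- grid_fit_oracle(pts)
  # constrained optimum: never worse than the grid search
  expect_lte(fit$sse, oracle$sse + 1e-6)
  expect_equal(unname(fit$ed50), oracle$ed50, tolerance = 0.05)
  expect_equal(fit$hillslope, oracle$slope, tolerance = 0.1)
})

test_that("scale equivariance: scaling doses scales ED50, not the slope", {
  set.seed(10)
  doses <- c(0.25, 0.75, 1.25, 1.75, 2.25)
  p <- hill_points(doses, ed50 = 1.4, slope = 4)
  p$hit_rate_percent <- pmin(100, pmax(0, p$hit_rate_percent + rnorm(5, 0, 5)))
  f1 <- fit_quantal(p)
  p2 <- p; p2$dose <- p$dose * 3
  f2 <- fit_quantal(p2)
  expect_equal(unname(f2$ed50), 3 * unname(f1$ed50), tolerance = 1e-4)
  expect_equal(f2$hillslope, f1$hillslope, tolerance = 1e-4)
})

test_that("degenerate sessions are dropped; fully degenerate input errors", {
  good <- hill_points(c(0.25, 0.75, 1.25, 1.75), ed50 = 1, slope = 2)
  flat <- data.frame(dose = c(0.25, 0.75), hit_rate_percent = c(100, 100),
                     n_trials = 10L)
  expect_warning(fit <- fit_quantal(list(good, flat)), "non-identifiable")
  expect_equal(fit$dropped_sessions, 2)
  expect_length(fit$ed50, 1)
  expect_error(suppressWarnings(fit_quantal(list(flat))), "no identifiable")
})

test_that("five identical sessions give zero between-session spread", {
  pts <- hill_points(c(0.25, 0.75, 1.25, 1.75, 2.25), ed50 = 1.6, slope = 3)
  fit <- fit_quantal(replicate(5, pts, simplify = FALSE))
  expect_equal(unname(fit$ed50), rep(1.6, 5), tolerance = 1e-5)
  expect_equal(fit$threshold_se, 0, tolerance = 1e-5)
})

test_that("end-to-end threshold estimation recovers a simulated animal", {
  obs <- observer_model(true_ed50 = 1.6, guess_rate = 0, lapse_rate = 0)
  logs <- lapply(81:83, function(s)
    run_session(session_config("ThresholdDetection", seed = s), obs))
  fit <- estimate_threshold(logs)
  expect_equal(fit$threshold_mean, 1.6, tolerance = 0.25)
  expect_true(all(fit$ed50 > 0))
  expect_true(is.finite(fit$hillslope))
})
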