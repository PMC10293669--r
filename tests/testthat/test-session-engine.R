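test_that("lockout voids pokes at or before 150 ms", {
  expect_equal(apply_lockout(c(0.05, 0.40)), 0.40)
  expect_equal(apply_lockout(numeric(0)), numeric(0))
  expect_equal(apply_lockout(0.150), numeric(0))  # boundary is inside the lockout
  expect_equal(apply_lockout(0.151), 0.151)
  expect_error(apply_lockout(-0.1), ">= 0")
})

test_that("classification follows the go/no-go outcome rules", {
  hit <- classify_response("stimulus", 1.0, hit_window_s = 3, trial_window_s = 6)
  expect_equal(hit$outcome, "hit")
  expect_false(hit$punished)
  expect_equal(hit$decision_time_s, 1.0)

  silent <- classify_response("stimulus", numeric(0), 3, 6)
  expect_equal(silent$outcome, "miss")
  expect_false(silent$punished)

  # first poke voided by the lockout; the next falls in the trial remainder
  late <- classify_response("stimulus", c(0.10, 4.5), 3, 6)
  expect_equal(late$outcome, "miss")
  expect_true(late$punished)
  expect_equal(late$decision_time_s, 4.5)

  expect_equal(classify_response("catch", numeric(0), 3, 6)$outcome,
               "correct_rejection")
  fa <- classify_response("catch", 2.0, 3, 6)
  expect_equal(fa$outcome, "false_alarm")
  expect_true(fa$punished)

  # hit-window boundary: a poke exactly at the hit window still rewards
  expect_equal(classify_response("stimulus", 3.0, 3, 6)$outcome, "hit")
  # pokes beyond the trial window are not responses
  expect_equal(classify_response("catch", 7.0, 3, 6)$outcome,
               "correct_rejection")
})

test_that("timeout pokes add air puffs and reset the remaining time", {
  expect_equal(run_timeout(8), list(total_s = 8, n_airpuffs = 1L))
  expect_equal(run_timeout(8, 4), list(total_s = 12, n_airpuffs = 2L))
  # hand trace: end 2 -> poke 1 resets to 3 -> poke 2.5 resets to 4.5
  expect_equal(run_timeout(2, c(1, 2.5)), list(total_s = 4.5, n_airpuffs = 3L))
  # a poke after the timeout has lapsed does not extend it
  expect_equal(run_timeout(2, 2.5), list(total_s = 2, n_airpuffs = 1L))
  expect_error(run_timeout(0), "> 0")
})

test_that("an always-detecting observer hits every stimulus trial", {
  obs <- step_observer(0.001)
  log <- run_session(session_config("Detection", seed = 3), obs)
  stim <- log$trials[log$trials$trial_type == "stimulus", ]
  catch <- log$trials[log$trials$trial_type == "catch", ]
  expect_true(all(stim$outcome == "hit"))
  expect_true(all(catch$outcome == "correct_rejection"))
  expect_equal(log$pellets, nrow(stim))
  # fixed 500 ms latency lands every hit at onset + 500 ms
  expect_true(all(stim$first_poke_ms == 500))
})

test_that("a never-poking observer misses out and trips the pause rule", {
  log <- run_session(session_config("Detection", seed = 5), never_poke_observer())
  expect_true(all(log$trials$outcome %in% c("miss", "correct_rejection")))
  expect_false(any(log$trials$punished))
  expect_equal(log$pellets, 0L)
  # pause engages after the 10th consecutive missed stimulus trial and,
  # with no poke ever coming, runs to the end of the session
  expect_true("pause_start" %in% log$events$kind)
  expect_equal(sum(log$trials$trial_type == "stimulus"), 10)
})

test_that("sessions are bit-identical under a fixed seed", {
  obs <- observer_model(true_ed50 = 1.6)
  cfg <- session_config("ThresholdDetection", seed = 21)
  a <- run_session(cfg, obs)
  b <- run_session(cfg, obs)
  expect_identical(a$trials, b$trials)
  expect_identical(a$events, b$events)
  c <- run_session(session_config("ThresholdDetection", seed = 22), obs)
  expect_false(identical(a$trials, c$trials))
})

test_that("outcomes partition trial types and pellets equal hits", {
  obs <- observer_model(true_ed50 = 1.6)
  for (phase in c("Shape2Detect", "Detection", "ThresholdDetection")) {
    log <- run_session(session_config(phase, seed = 31), obs)
    tr <- log$trials
    stim <- tr$trial_type %in% c("stimulus", "naive_anchor", "dynamic")
    expect_true(all(tr$outcome[stim] %in% c("hit", "miss")))
    expect_true(all(tr$outcome[tr$trial_type == "catch"] %in%
                      c("false_alarm", "correct_rejection")))
    expect_equal(log$pellets, sum(tr$outcome == "hit"))
  }
})

test_that("trial windows never overlap and inter-trial periods hold", {
  obs <- observer_model(true_ed50 = 1.6, timeout_poke_prob = 0.3)
  log <- run_session(session_config("Detection", seed = 41), obs)
  tr <- log$trials
  # reconstruct each trial's end from its decision/window plus timeout
  dec_ms <- vapply(tr$poke_times_ms, function(p) {
    eff <- p[p > 150 & p <= 6000]
    if (length(eff)) min(eff) else 6000
  }, 0)
  end_ms <- tr$trial_start_ms + round(dec_ms + tr$timeout_s * 1000)
  gaps <- tr$trial_start_ms[-1] - end_ms[-nrow(tr)]
  expect_true(all(gaps >= 3000))
  expect_lte(max(tr$trial_start_ms) + 6000, 60 * 60000)
})

test_that("replaying logged pokes reproduces the recorded outcomes", {
  obs <- observer_model(true_ed50 = 1.6)
  log <- run_session(session_config("ThresholdDetection", seed = 51), obs)
  tr <- log$trials
  for (i in seq_len(nrow(tr))) {
    par <- lookup_params(tr$phase[i], tr$minute[i])
    cls <- classify_response(
      if (tr$trial_type[i] == "catch") "catch" else "stimulus",
      tr$poke_times_ms[[i]] / 1000, par$hit_window_s, par$trial_window_s)
    expect_equal(cls$outcome, tr$outcome[i])
    expect_equal(cls$punished, tr$punished[i])
  }
})

test_that("Shaping rewards every effective poke in indefinite windows", {
  obs <- observer_model(true_ed50 = 1.6, shaping_mean_latency_s = 10)
  log <- run_session(session_config("Shaping", seed = 61), obs)
  expect_true(all(log$trials$outcome == "hit"))
  expect_true(all(log$trials$first_poke_ms > 150))
  expect_equal(log$pellets, nrow(log$trials))
  expect_gte(log$pellets, 100)  # an engaged animal passes the shaping gate
})
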