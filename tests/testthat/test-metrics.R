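test_that("zero-count correction moves 0.5 within each pair", {
  adj <- zero_correct(new_counts(119, 0, 30, 40))
  expect_equal(unlist(unclass(adj)),
               c(hits = 118.5, misses = 0.5, false_alarms = 30,
                 correct_rejections = 40))

  untouched <- zero_correct(new_counts(50, 10, 5, 60))
  expect_equal(unlist(unclass(untouched)),
               c(hits = 50, misses = 10, false_alarms = 5,
                 correct_rejections = 60))

  both <- zero_correct(new_counts(0, 20, 20, 0))
  expect_equal(unlist(unclass(both)),
               c(hits = 0.5, misses = 19.5, false_alarms = 19.5,
                 correct_rejections = 0.5))

  expect_error(zero_correct(new_counts(0, 0, 5, 5)), "both pair members")
})

test_that("zero-count correction conserves pair sums", {
  set.seed(5)
  for (rep in 1:50) {
    raw <- new_counts(rpois(1, 3) * rbinom(1, 1, 0.7), rpois(1, 3),
                      rpois(1, 2), rpois(1, 40) + 1)
    adj <- try(zero_correct(raw), silent = TRUE)
    if (inherits(adj, "try-error")) next
    expect_equal(adj$hits + adj$misses, raw$hits + raw$misses)
    expect_equal(adj$false_alarms + adj$correct_rejections,
                 raw$false_alarms + raw$correct_rejections)
    expect_true(all(unlist(unclass(adj)) > 0))
  }
})

test_that("performance scores implement the six task metrics", {
  sc <- performance_scores(new_counts(49.5, 0.5, 0.5, 49.5))
  expect_equal(sc$accuracy, 0.99)
  expect_equal(sc$hit_rate, 0.99)

  chance <- performance_scores(new_counts(30, 30, 25, 25))
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$d_prime, 0)

  adj <- zero_correct(new_counts(119, 0, 30, 40))
  expect_equal(performance_scores(adj)$hit_rate, 118.5 / 119)

  sc <- performance_scores(new_counts(80, 20, 10, 90))
  expect_equal(sc$precision, 80 / 90)
  expect_equal(sc$correct_rejection_rate, 0.9)
  expect_equal(sc$f1, 2 * (80 / 90) * 0.8 / (80 / 90 + 0.8))
  expect_equal(sc$accuracy, 170 / 200)
})

test_that("accuracy is invariant under exchanging H<->CR and M<->FA", {
  a <- performance_scores(new_counts(70, 10, 5, 90))
  b <- performance_scores(new_counts(90, 5, 10, 70))
  expect_equal(a$accuracy, b$accuracy)
})

test_that("d-prime is the quantile difference and is antisymmetric", {
  expect_equal(d_prime(0.5, 0.5), 0)
  expect_equal(d_prime(0.9, 0.1), 2 * qnorm(0.9))
  expect_equal(d_prime(0.9, 0.1), 2.5631, tolerance = 1e-4)
  expect_equal(d_prime(0.1, 0.9), -d_prime(0.9, 0.1))
  set.seed(6)
  for (rep in 1:20) {
    h <- runif(1, 0.01, 0.99); f <- runif(1, 0.01, 0.99)
    expect_equal(d_prime(h, f), -d_prime(f, h))
  }
  expect_error(d_prime(1, 0.5), "zero-count")
  expect_error(d_prime(0.5, 0), "zero-count")
})

test_that("confusion counts exclude distracted trials", {
  tr <- data.frame(
    trial_type = c("stimulus", "stimulus", "catch", "catch", "dynamic"),
    outcome = c("hit", "miss", "false_alarm", "correct_rejection", "hit"),
    distracted = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  cc <- confusion_counts(tr)
  expect_equal(unlist(unclass(cc)),
               c(hits = 2, misses = 0, false_alarms = 1,
                 correct_rejections = 1))
})

test_that("counting agrees with a brute-force recount on random sessions", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    stim <- runif(n) < 0.5
    tr <- data.frame(
      trial_type = ifelse(stim, "stimulus", "catch"),
      outcome = ifelse(stim,
                       ifelse(runif(n) < 0.8, "hit", "miss"),
                       ifelse(runif(n) < 0.2, "false_alarm", "correct_rejection")),
      distracted = runif(n) < 0.1)
    cc <- confusion_counts(tr)
    expect_equal(unlist(unclass(cc)), recount_oracle(tr))
  }
})

test_that("tier proficiency gates apply their criteria", {
  det <- data.frame(accuracy = rep(0.8, 3), precision = rep(0.8, 3),
                    hit_rate = rep(0.8, 3),
                    correct_rejection_rate = rep(0.8, 3),
                    f1 = rep(0.8, 3), d_prime = rep(2, 3))
  expect_true(proficiency("Detection", det)$pass)
  det2 <- det; det2$d_prime[2] <- 1.2
  expect_false(proficiency("Detection", det2)$pass)

  s2d <- data.frame(accuracy = c(0.8, 0.74), precision = c(0.9, 0.9),
                    hit_rate = c(0.9, 0.9), pellets = c(120, 120))
  res <- proficiency("Shape2Detect", s2d)
  expect_false(res$pass)
  expect_equal(res$reasons, "accuracy")

  # 100 pellets once, then 90: the two-consecutive rule fails
  shp <- data.frame(pellets = c(100, 90), manual_dispenses = c(0, 0))
  expect_false(proficiency("Shaping", shp)$pass)
  shp2 <- data.frame(pellets = c(90, 100, 110), manual_dispenses = c(0, 0, 0))
  expect_true(proficiency("Shaping", shp2)$pass)
  shp3 <- data.frame(pellets = c(120, 120), manual_dispenses = c(0, 2))
  expect_false(proficiency("Shaping", shp3)$pass)
  expect_error(proficiency("Expert", shp), "unknown tier")
})

test_that("pooled confusion matrix is presented-by-response", {
  tr <- data.frame(
    trial_type = c("stimulus", "stimulus", "stimulus", "catch", "catch"),
    outcome = c("hit", "hit", "miss", "false_alarm", "correct_rejection"),
    distracted = FALSE)
  cm <- pooled_confusion(tr)
  expect_equal(dim(cm), c(2, 2))
  expect_equal(cm["stimulus", "poke"], 2)
  expect_equal(cm["stimulus", "no_poke"], 1)
  expect_equal(cm["catch", "poke"], 1)
  expect_equal(cm["catch", "no_poke"], 1)
})
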