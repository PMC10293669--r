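# Shared helpers: independent oracles and canned observers.

# Deterministic step observer: detects iff intensity >= threshold, fixed
# latency, no guessing/lapsing/distraction.
step_observer <- function(threshold, latency_ms = 500) {
  observer_model(true_ed50 = threshold, slope = Inf,
                 guess_rate = 0, lapse_rate = 0,
                 latency_mean_ms = latency_ms, latency_sd_ms = 0,
                 distraction_rate = 0)
}

# Observer that never pokes: detection probability ~0 everywhere in range,
# no spontaneous pokes.
never_poke_observer <- function() {
  observer_model(true_ed50 = 1e9, slope = 12, guess_rate = 0,
                 lapse_rate = 0, distraction_rate = 0)
}

# Brute-force recount of confusion counts from raw trial records,
# independent of confusion_counts().
recount_oracle <- function(trials) {
  h <- m <- fa <- cr <- 0
  for (i in seq_len(nrow(trials))) {
    if (isTRUE(trials$distracted[i])) next
    o <- trials$outcome[i]
    if (o == "hit") h <- h + 1
    if (o == "miss") m <- m + 1
    if (o == "false_alarm") fa <- fa + 1
    if (o == "correct_rejection") cr <- cr + 1
  }
  c(hits = h, misses = m, false_alarms = fa, correct_rejections = cr)
}

# Independent grid-search minimizer for the shared-slope Hill fit. Given
# the slope, the per-session SSE minimizations are separable, so the joint
# optimum over the grid is the slope-wise sum of per-session minima.
grid_fit_oracle <- function(points_by_session, n_slope = 120, n_ed50 = 200) {
  slopes <- exp(seq(log(0.1), log(20), length.out = n_slope))
  doses <- unlist(lapply(points_by_session, `[[`, "dose"))
  ed50s <- exp(seq(log(min(doses) / 4), log(max(doses) * 4),
                   length.out = n_ed50))
  best <- list(sse = Inf)
  for (s in slopes) {
    sse_s <- 0
    e_s <- numeric(length(points_by_session))
    for (j in seq_along(points_by_session)) {
      pts <- points_by_session[[j]]
      sse_j <- vapply(ed50s, function(e) {
        r <- (pts$dose / e)^s
        sum((pts$hit_rate_percent - 100 * r / (1 + r))^2)
      }, 0)
      k <- which.min(sse_j)
      sse_s <- sse_s + sse_j[k]
      e_s[j] <- ed50s[k]
    }
    if (sse_s < best$sse) best <- list(sse = sse_s, slope = s, ed50 = e_s)
  }
  best
}

# Noiseless dose-response points from a Hill curve.
hill_points <- function(doses, ed50, slope) {
  data.frame(dose = doses,
             hit_rate_percent = 100 * (doses / ed50)^slope /
               (1 + (doses / ed50)^slope),
             n_trials = 20L)
}
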