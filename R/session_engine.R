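#' Remove pokes voided by the post-stimulus lockout
#'
#' The nose-poke sensor does not trigger during the first 150 ms of a
#' trial, to discard accidental pokes at trial onset. Pokes at or before
#' the lockout boundary are voided (the boundary itself is inside the
#' lockout; one boundary convention had to be fixed, and it is tested).
#'
#' @param poke_times_s Poke times in seconds relative to trial start.
#' @param lockout_s Lockout duration, seconds (default 0.15).
#' @return The effective poke times (those strictly after the lockout).
#' @examples
#' apply_lockout(c(0.05, 0.40)) # 0.40
#' @export
apply_lockout <- function(poke_times_s, lockout_s = 0.15) {
  if (any(poke_times_s < 0)) stop("poke times must be >= 0", call. = FALSE)
  poke_times_s[poke_times_s > lockout_s]
}

#' Classify a trial's outcome from its pokes
#'
#' Go/no-go outcome classification. On a stimulus-bearing trial, the first
#' effective poke (after the 150 ms lockout) within the hit window is a
#' hit; a first effective poke in the trial remainder is a miss with
#' punishment (air puff + timeout); no effective poke is an unpunished
#' miss. On a catch trial any effective poke in the window is a false
#' alarm with punishment; none is a correct rejection.
#'
#' @param trial_type `"stimulus"` (also used for anchor/dynamic trials) or
#'   `"catch"`.
#' @param poke_times_s Poke times in seconds relative to trial start
#'   (lockout is applied here; passing pre-filtered times is harmless).
#' @param hit_window_s Hit window, seconds.
#' @param trial_window_s Trial window, seconds.
#' @param lockout_s Lockout, seconds.
#' @return A list: `outcome` (one of `"hit"`, `"miss"`, `"false_alarm"`,
#'   `"correct_rejection"`), `punished` (logical), `decision_time_s` (time
#'   of the deciding poke, or `NA` when no effective poke occurred).
#' @examples
#' classify_response("stimulus", 1.0, hit_window_s = 3, trial_window_s = 6)$outcome
#' @export
classify_response <- function(trial_type, poke_times_s, hit_window_s,
                              trial_window_s, lockout_s = 0.15) {
  if (!trial_type %in% c("stimulus", "catch")) {
    stop("trial_type must be 'stimulus' or 'catch'", call. = FALSE)
  }
  eff <- apply_lockout(poke_times_s, lockout_s)
  eff <- sort(eff[eff <= trial_window_s])
  first <- if (length(eff)) eff[1] else NA_real_
  if (trial_type == "catch") {
    if (is.na(first)) {
      return(list(outcome = "correct_rejection", punished = FALSE,
                  decision_time_s = NA_real_))
    }
    return(list(outcome = "false_alarm", punished = TRUE,
                decision_time_s = first))
  }
  if (is.na(first)) {
    return(list(outcome = "miss", punished = FALSE, decision_time_s = NA_real_))
  }
  if (first <= hit_window_s) {
    return(list(outcome = "hit", punished = FALSE, decision_time_s = first))
  }
  list(outcome = "miss", punished = TRUE, decision_time_s = first)
}

#' Serve a timeout period, with poke-driven extensions
#'
#' A punished response triggers an air puff and a red-light timeout of the
#' scheduled base duration. Each poke during the active timeout earns an
#' additional air puff and resets the remaining timeout to the full base
#' duration (the escalation rule).
#'
#' @param base_timeout_s Scheduled timeout duration, seconds (> 0).
#' @param poke_times_s Poke times in seconds relative to timeout start.
#' @return A list: `total_s` (time served) and `n_airpuffs` (including the
#'   puff for the response that triggered the timeout).
#' @examples
#' run_timeout(8, 4) # 12 s, 2 puffs
#' @export
run_timeout <- function(base_timeout_s, poke_times_s = numeric(0)) {
  if (base_timeout_s <= 0) stop("base_timeout_s must be > 0", call. = FALSE)
  end <- base_timeout_s
  puffs <- 1L
  for (p in sort(poke_times_s)) {
    if (p < end) {
      end <- p + base_timeout_s
      puffs <- puffs + 1L
    }
  }
  list(total_s = end, n_airpuffs = puffs)
}

# Geometric draw of timeout pokes for the simulated observer: each active
# base period carries one poke with prob timeout_poke_prob, placed uniformly.
simulate_timeout_pokes <- function(observer, base_timeout_s, max_pokes = 5L) {
  pokes <- numeric(0)
  start <- 0
  while (length(pokes) < max_pokes &&
         stats::runif(1) < observer$timeout_poke_prob) {
    p <- start + stats::runif(1, 0, base_timeout_s)
    pokes <- c(pokes, p)
    start <- p
  }
  pokes
}

#' Session configuration
#'
#' Bundles the phase, modality, intensities and engine options for one
#' simulated 1-h session. Defaults reproduce the published task
#' parameters; the schedules themselves come from [lookup_params()],
#' [sample_trial_type()] and [step_size()].
#'
#' @param phase `"Shaping"`, `"Shape2Detect"`, `"Detection"` or
#'   `"ThresholdDetection"`.
#' @param modality `"icms"` or `"auditory"`.
#' @param naive_intensity The naive perception threshold used as the
#'   training intensity and staircase anchor: nC/ph for ICMS (3--4 in
#'   practice), percent amplitude for auditory (100 = training tone).
#' @param seed Integer seed; one RNG stream per session, recorded in the log.
#' @param session_minutes Session length in minutes.
#' @param jitter Logical; apply uniform jitter to staircase steps.
#' @param iti_s Inter-trial period (white light), seconds.
#' @param lockout_s Post-onset lockout, seconds.
#' @param pause_after_misses Consecutive unanswered stimulus trials that
#'   pause the session until the next poke.
#' @return An object of class `session_config`.
#' @export
session_config <- function(phase = "Detection",
                           modality = c("icms", "auditory"),
                           naive_intensity = if (match.arg(modality) == "icms") 3 else 100,
                           seed = 1L,
                           session_minutes = 60,
                           jitter = TRUE,
                           iti_s = 3,
                           lockout_s = 0.15,
                           pause_after_misses = 10L) {
  check_phase(phase)
  modality <- match.arg(modality)
  if (naive_intensity <= 0) {
    stop("naive_intensity must be > 0", call. = FALSE)
  }
  structure(
    list(phase = phase, modality = modality,
         naive_intensity = naive_intensity, seed = as.integer(seed),
         session_minutes = session_minutes, jitter = jitter,
         iti_s = iti_s, lockout_s = lockout_s,
         pause_after_misses = as.integer(pause_after_misses)),
    class = "session_config"
  )
}

#' Run one simulated session
#'
#' Sequences the trial state machine for a 1-h session: a 3 s white-light
#' inter-trial period precedes each green-light trial window; trial types
#' are sampled from the phase schedule; the observer's pokes are classified
#' into hit / miss / false alarm / correct rejection; punished responses
#' trigger air puffs and extendable timeouts; ten consecutive unanswered
#' stimulus trials pause the session until the observer pokes again (catch
#' trials neither advance nor reset the counter). In the threshold task the
#' dynamic intensity follows the modified up/down staircase. Shaping runs
#' indefinite trial windows and rewards any effective poke.
#'
#' @param config A [session_config()].
#' @param observer An [observer_model()].
#' @return An object of class `session_log`: a list with `config`,
#'   `observer` (ground truth echoed for recovery tests), `seed`, `trials`
#'   (a data.frame; see [write_session_log()] for columns), `events`
#'   (a data.frame of timestamped symbolic events), and for threshold
#'   sessions `staircase` (the final [init_staircase()] state with its
#'   trajectory).
#' @examples
#' log <- run_session(session_config("Detection", seed = 7),
#'                    observer_model(true_ed50 = 1.6))
#' table(log$trials$outcome)
#' @export
run_session <- function(config, observer) {
  stopifnot(inherits(config, "session_config"),
            inherits(observer, "observer_model"))
  set.seed(config$seed)
  phase <- config$phase
  end_ms <- config$session_minutes * 60000
  stair <- if (phase == "ThresholdDetection") init_staircase(config$naive_intensity)

  trials <- vector("list", 1024L)
  events <- vector("list", 4096L)
  n_tr <- 0L; n_ev <- 0L
  add_event <- function(t_ms, kind, trial = NA_integer_) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * n_ev
    events[[n_ev]] <<- list(t_ms = t_ms, kind = kind, trial_index = trial)
  }

  t <- config$iti_s * 1000  # initial white-light period
  consec_unanswered <- 0L
  pellets <- 0L

  repeat {
    par <- lookup_params(phase, min(floor(t / 60000), config$session_minutes - 1))
    window_ms <- if (is.finite(par$trial_window_s)) par$trial_window_s * 1000 else 0
    if (t + window_ms >= end_ms) break
    minute <- floor(t / 60000)
    type <- sample_trial_type(phase, minute)
    intensity <- switch(
      type,
      shaping = NA_real_,
      catch = NA_real_,
      stimulus = config$naive_intensity,
      naive_anchor = config$naive_intensity,
      dynamic = stair$dynamic_intensity
    )
    resp <- observer_respond(observer, type, intensity,
                             trial_window_s = par$trial_window_s,
                             hit_window_s = par$hit_window_s)
    # integer-millisecond time base: quantize pokes before classification
    # so the logged poke times reproduce the recorded outcomes exactly
    resp$poke_times_s <- round(resp$poke_times_s * 1000) / 1000
    n_tr <- n_tr + 1L
    if (n_tr > length(trials)) length(trials) <- 2L * n_tr
    add_event(t, "trial_start", n_tr)
    for (p in resp$poke_times_s) add_event(t + round(p * 1000), "poke", n_tr)

    if (phase == "Shaping") {
      # Indefinite window; any effective poke is rewarded.
      poke <- resp$poke_times_s[1]
      if (t + poke * 1000 >= end_ms) { n_tr <- n_tr - 1L; break }
      outcome <- "hit"; punished <- FALSE
      decision <- poke
      timeout_total <- 0; puffs <- 0L
      trial_end_rel <- poke
    } else {
      cls <- classify_response(if (type == "catch") "catch" else "stimulus",
                               resp$poke_times_s, par$hit_window_s,
                               par$trial_window_s, config$lockout_s)
      outcome <- cls$outcome; punished <- cls$punished
      decision <- cls$decision_time_s
      # A deciding poke (reward or punishment) ends the trial there.
      trial_end_rel <- if (is.na(decision)) par$trial_window_s else decision
      timeout_total <- 0; puffs <- 0L
      if (punished) {
        tp <- simulate_timeout_pokes(observer, par$timeout_s)
        for (p in tp) add_event(t + round((trial_end_rel + p) * 1000), "poke", n_tr)
        to <- run_timeout(par$timeout_s, tp)
        timeout_total <- to$total_s; puffs <- to$n_airpuffs
        add_event(t + round(trial_end_rel * 1000), "timeout_start", n_tr)
        for (k in seq_len(puffs)) add_event(t + round(trial_end_rel * 1000), "airpuff", n_tr)
      }
      if (type == "dynamic") {
        stair <- staircase_update(stair, outcome, minute, config$modality,
                                  jitter = config$jitter)
      }
    }
    if (outcome == "hit") {
      pellets <- pellets + 1L
      add_event(t + round(trial_end_rel * 1000), "pellet", n_tr)
    }

    first_poke_ms <- if (length(resp$poke_times_s)) {
      round(resp$poke_times_s[1] * 1000)
    } else NA_real_
    trials[[n_tr]] <- list(
      trial_index = n_tr, phase = phase, minute = minute, trial_type = type,
      intensity_value = intensity,
      intensity_units = if (type %in% c("catch", "shaping")) "" else intensity_units(config$modality),
      outcome = outcome, first_poke_ms = first_poke_ms,
      poke_times_ms = round(resp$poke_times_s * 1000),
      punished = punished, timeout_s = timeout_total,
      n_airpuffs = puffs, distracted = resp$distracted,
      trial_start_ms = t
    )

    # 10-miss pause rule: only stimulus-bearing trials count; any poke resets.
    answered <- length(resp$poke_times_s) > 0
    if (answered) {
      consec_unanswered <- 0L
    } else if (!type %in% c("catch", "shaping")) {
      consec_unanswered <- consec_unanswered + 1L
    }

    t <- t + round((trial_end_rel + timeout_total) * 1000) + config$iti_s * 1000

    if (consec_unanswered >= config$pause_after_misses && t < end_ms) {
      add_event(t, "pause_start", NA_integer_)
      if (observer$guess_rate > 0) {
        hazard_hz <- observer$guess_rate / par$trial_window_s
        wait_ms <- round(stats::rexp(1, hazard_hz) * 1000)
        t <- min(t + wait_ms, end_ms)
        if (t < end_ms) add_event(t, "poke", NA_integer_)
      } else {
        t <- end_ms  # a never-poking observer stays paused to session end
      }
      add_event(t, "pause_end", NA_integer_)
      consec_unanswered <- 0L
    }
    if (t >= end_ms) break
  }

  trials <- trials[seq_len(n_tr)]
  trial_df <- if (n_tr) {
    df <- do.call(rbind, lapply(trials, function(x) {
      data.frame(x[setdiff(names(x), "poke_times_ms")],
                 stringsAsFactors = FALSE)
    }))
    df$poke_times_ms <- lapply(trials, `[[`, "poke_times_ms")
    rownames(df) <- NULL
    df
  } else {
    empty_trials_df()
  }
  ev <- events[seq_len(n_ev)]
  event_df <- if (n_ev) {
    data.frame(t_ms = vapply(ev, `[[`, 0, "t_ms"),
               kind = vapply(ev, `[[`, "", "kind"),
               trial_index = vapply(ev, `[[`, 0L, "trial_index"))
  } else {
    data.frame(t_ms = numeric(0), kind = character(0),
               trial_index = integer(0))
  }
  event_df <- event_df[order(event_df$t_ms), , drop = FALSE]
  rownames(event_df) <- NULL

  structure(
    list(config = config, observer = observer, seed = config$seed,
         trials = trial_df, events = event_df, pellets = pellets,
         manual_dispenses = 0L,
         staircase = if (phase == "ThresholdDetection") stair),
    class = "session_log"
  )
}

empty_trials_df <- function() {
  df <- data.frame(trial_index = integer(0), phase = character(0),
                   minute = numeric(0), trial_type = character(0),
                   intensity_value = numeric(0), intensity_units = character(0),
                   outcome = character(0), first_poke_ms = numeric(0),
                   punished = logical(0), timeout_s = numeric(0),
                   n_airpuffs = integer(0), distracted = logical(0),
                   trial_start_ms = numeric(0), stringsAsFactors = FALSE)
  df$poke_times_ms <- list()
  df
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: %s (%s), seed %d, %d trials, %d pellets\n",
              x$config$phase, x$config$modality, x$seed,
              nrow(x$trials), x$pellets))
  if (nrow(x$trials)) print(table(x$trials$outcome))
  invisible(x)
}
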