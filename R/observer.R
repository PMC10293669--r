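#' Simulated rat observer
#'
#' A synthetic observer whose probability of detecting a stimulus follows a
#' Hill-type psychometric function of intensity, mixed with guessing and
#' lapsing, plus spontaneous poking, poke latency, and occasional
#' distraction. Because the detection model shares the functional form of
#' the quantal dose-response curve used for threshold estimation, parameter
#' recovery from simulated sessions is well-posed.
#'
#' `slope = Inf` gives a deterministic step observer that detects exactly
#' when `intensity >= true_ed50`, useful for hand-traceable staircase tests.
#'
#' @param true_ed50 Ground-truth 50%-detection intensity (nC/ph or
#'   percent amplitude, per the session modality). Must be > 0.
#' @param slope Hill slope of the psychometric function (> 0, may be `Inf`).
#'   The default of 6 places detection at a 3 nC/ph training intensity
#'   (with `true_ed50 = 1.6`) in the ~95% hit-rate proficiency regime.
#' @param guess_rate Probability of a spontaneous poke per trial window
#'   (drives false alarms on catch trials).
#' @param lapse_rate Probability of ignoring a detected stimulus.
#' @param latency_mean_ms,latency_sd_ms Poke latency after stimulus onset:
#'   normal distribution truncated to `(0, hit_window]`. `latency_sd_ms = 0`
#'   gives a fixed latency.
#' @param distraction_rate Per-trial probability the trial is annotated
#'   distracted (excluded from metrics downstream).
#' @param timeout_poke_prob Probability of poking during an active timeout
#'   period (each poke extends the timeout); 0 disables.
#' @param shaping_mean_latency_s Mean of the exponential poke latency
#'   (beyond the 150 ms lockout) during Shaping's indefinite trial windows.
#' @return An object of class `observer_model`.
#' @examples
#' obs <- observer_model(true_ed50 = 1.6)
#' detection_probability(1.6, observer_model(1.6, guess_rate = 0, lapse_rate = 0))
#' @export
observer_model <- function(true_ed50,
                           slope = 6,
                           guess_rate = 0.05,
                           lapse_rate = 0.05,
                           latency_mean_ms = 800,
                           latency_sd_ms = 300,
                           distraction_rate = 0.02,
                           timeout_poke_prob = 0,
                           shaping_mean_latency_s = 15) {
  if (true_ed50 <= 0) stop("true_ed50 must be > 0", call. = FALSE)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  for (p in c(guess_rate, lapse_rate, distraction_rate, timeout_poke_prob)) {
    if (p < 0 || p >= 1) {
      stop("rates must lie in [0, 1)", call. = FALSE)
    }
  }
  if (guess_rate + lapse_rate >= 1) {
    stop("guess_rate + lapse_rate must be < 1", call. = FALSE)
  }
  structure(
    list(true_ed50 = true_ed50, slope = slope,
         guess_rate = guess_rate, lapse_rate = lapse_rate,
         latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
         distraction_rate = distraction_rate,
         timeout_poke_prob = timeout_poke_prob,
         shaping_mean_latency_s = shaping_mean_latency_s),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf(
    "Simulated observer: ED50 = %g, slope = %g, guess = %g, lapse = %g, latency %g +/- %g ms\n",
    x$true_ed50, x$slope, x$guess_rate, x$lapse_rate,
    x$latency_mean_ms, x$latency_sd_ms))
  invisible(x)
}

#' Detection probability of the simulated observer
#'
#' `p = guess + (1 - guess - lapse) * x^s / (ED50^s + x^s)`, the Hill
#' psychometric function compressed between the guess and lapse asymptotes.
#' With `slope = Inf` the core term is a step: 1 when `x >= ED50`, else 0.
#'
#' @param intensity Stimulus intensity (vectorized, >= 0).
#' @param observer An [observer_model()].
#' @return Detection probability in `[0, 1]`.
#' @export
detection_probability <- function(intensity, observer) {
  stopifnot(inherits(observer, "observer_model"))
  if (any(intensity < 0)) stop("intensity must be >= 0", call. = FALSE)
  if (is.infinite(observer$slope)) {
    core <- as.numeric(intensity >= observer$true_ed50)
  } else {
    r <- (intensity / observer$true_ed50)^observer$slope
    core <- ifelse(is.infinite(r), 1, r / (1 + r))
    core[intensity == 0] <- 0
  }
  observer$guess_rate + (1 - observer$guess_rate - observer$lapse_rate) * core
}

# Truncated-normal latency draw on (0, hit_window] seconds, in ms.
draw_latency_ms <- function(observer, hit_window_s) {
  if (observer$latency_sd_ms == 0) {
    return(min(observer$latency_mean_ms, hit_window_s * 1000))
  }
  upper_ms <- hit_window_s * 1000
  lo <- stats::pnorm(0, observer$latency_mean_ms, observer$latency_sd_ms)
  hi <- stats::pnorm(upper_ms, observer$latency_mean_ms, observer$latency_sd_ms)
  u <- stats::runif(1, lo, hi)
  stats::qnorm(u, observer$latency_mean_ms, observer$latency_sd_ms)
}

#' Generate the observer's pokes for one trial
#'
#' Stimulus-bearing trials: with probability [detection_probability()] the
#' observer pokes at stimulus onset plus a latency draw (truncated normal
#' on `(0, hit_window]`). Otherwise -- and on catch trials -- a spontaneous
#' poke occurs with probability `guess_rate`, uniformly within the trial
#' window (at most one; the first poke decides the outcome). A distraction
#' flag is drawn independently per trial.
#'
#' @param observer An [observer_model()].
#' @param trial_type `"stimulus"`, `"naive_anchor"`, `"dynamic"`, `"catch"`,
#'   or `"shaping"`.
#' @param intensity Presented intensity (ignored for catch/shaping trials).
#' @param trial_window_s Trial window duration, seconds.
#' @param hit_window_s Hit window duration, seconds.
#' @return A list: `poke_times_s` (relative to trial start) and `distracted`.
#' @export
observer_respond <- function(observer, trial_type, intensity,
                             trial_window_s, hit_window_s) {
  stopifnot(inherits(observer, "observer_model"))
  distracted <- stats::runif(1) < observer$distraction_rate
  if (trial_type == "shaping") {
    # Indefinite green-light window: poke after the lockout plus an
    # exponential exploration latency.
    poke <- 0.15 + stats::rexp(1, 1 / observer$shaping_mean_latency_s)
    return(list(poke_times_s = poke, distracted = distracted))
  }
  pokes <- numeric(0)
  detected <- FALSE
  if (trial_type != "catch") {
    p <- detection_probability(intensity, observer)
    detected <- stats::runif(1) < p
    if (detected) {
      pokes <- draw_latency_ms(observer, hit_window_s) / 1000
    }
  }
  if (!detected && stats::runif(1) < observer$guess_rate) {
    pokes <- stats::runif(1, 0, trial_window_s)
  }
  list(poke_times_s = pokes, distracted = distracted)
}
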