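#' Shape2Detect session schedule
#'
#' The piecewise-constant behavioral parameters of the second training tier,
#' varied over the 1-h session. Trial windows lengthen from 3 s to 6 s, the
#' stimulus-trial probability falls from 83.3% to 50%, and hit windows and
#' timeouts change per segment. Segments are half-open `[start, end + 1)` on
#' integer minutes, matching the printed ranges.
#'
#' @return A data.frame with columns `start_min`, `end_min` (inclusive label),
#'   `trial_window_s`, `stimulus_probability`, `hit_window_s`, `timeout_s`.
#' @export
shape2detect_schedule <- function() {
  data.frame(
    start_min = c(0, 10, 20, 30, 40),
    end_min = c(9, 19, 29, 39, 60),
    trial_window_s = c(3, 3, 4, 5, 6),
    stimulus_probability = c(0.833, 0.714, 0.667, 0.600, 0.500),
    hit_window_s = c(3, 3, 4, 5, 3),
    timeout_s = c(2, 3, 3, 5, 8)
  )
}

#' Detection-phase constants
#'
#' The fixed parameters of the third training tier (and of the threshold
#' detection task, which keeps them): 6 s trial window, 3 s hit window, 50%
#' stimulus-trial probability, 8 s timeouts.
#'
#' @return A one-row data.frame with the same columns as
#'   [shape2detect_schedule()] minus the time range.
#' @export
detection_params <- function() {
  data.frame(trial_window_s = 6, stimulus_probability = 0.5,
             hit_window_s = 3, timeout_s = 8)
}

#' Staircase step-size schedule
#'
#' Step size variation for the dynamic stimulus intensity over a 1-h
#' threshold-detection session, per modality. The first 20 minutes carry no
#' variation (the staircase is frozen); later segments shrink the step.
#' `halfwidth` is the printed "+/-" jitter half-range around the central step.
#'
#' @return A data.frame with columns `start_min`, `end_min`, `modality`
#'   (`"icms"` in nC/ph, `"auditory"` in percent amplitude), `central_step`,
#'   `halfwidth`.
#' @export
step_schedule <- function() {
  data.frame(
    start_min = rep(c(20, 30, 40, 50), 2),
    end_min = rep(c(29, 39, 49, 60), 2),
    modality = rep(c("icms", "auditory"), each = 4),
    central_step = c(1.00, 0.60, 0.40, 0.20, 20.00, 10.00, 1.00, 0.10),
    halfwidth = c(0.40, 0.20, 0.10, 0.05, 5.00, 3.00, 0.30, 0.03)
  )
}

phase_names <- c("Shaping", "Shape2Detect", "Detection", "ThresholdDetection")

check_phase <- function(phase) {
  if (!is.character(phase) || length(phase) != 1 || !phase %in% phase_names) {
    stop("unknown phase; expected one of: ", paste(phase_names, collapse = ", "),
         call. = FALSE)
  }
  phase
}

#' Look up session parameters for a phase and minute
#'
#' Returns the behavioral parameters governing the given session minute:
#' the covering [shape2detect_schedule()] row for Shape2Detect, the fixed
#' [detection_params()] for Detection and ThresholdDetection. The lookup is
#' right-continuous at segment boundaries (minute 10 uses the 10--19 row).
#' Shaping has an indefinite trial window and no stimulus, encoded as
#' `trial_window_s = Inf` and `stimulus_probability = 0`.
#'
#' @param phase One of `"Shaping"`, `"Shape2Detect"`, `"Detection"`,
#'   `"ThresholdDetection"`.
#' @param session_time_min Session time in minutes, `0 <= t < 60`.
#' @return A one-row data.frame: `trial_window_s`, `stimulus_probability`,
#'   `hit_window_s`, `timeout_s`.
#' @examples
#' lookup_params("Shape2Detect", 15) # 3 s window, 0.714, 3 s hit, 3 s timeout
#' @export
lookup_params <- function(phase, session_time_min) {
  check_phase(phase)
  if (session_time_min < 0 || session_time_min >= 60) {
    stop("session_time_min outside the 1-h session: must satisfy 0 <= t < 60",
         call. = FALSE)
  }
  if (phase == "Shaping") {
    return(data.frame(trial_window_s = Inf, stimulus_probability = 0,
                      hit_window_s = Inf, timeout_s = 0))
  }
  if (phase %in% c("Detection", "ThresholdDetection")) {
    return(detection_params())
  }
  sched <- shape2detect_schedule()
  m <- floor(session_time_min)
  row <- sched[sched$start_min <= m & m <= sched$end_min, , drop = FALSE]
  row[1, c("trial_window_s", "stimulus_probability", "hit_window_s", "timeout_s")]
}

#' Sample trial types for a phase and minute
#'
#' Training phases present `"stimulus"` trials with the scheduled
#' probability, else `"catch"`. The threshold-detection task presents the
#' naive-threshold anchor with 50% probability (vs catch) during minutes
#' 0--19, then an equal 1/3 mixture of `"naive_anchor"`, `"dynamic"` and
#' `"catch"` for the remainder of the session.
#'
#' @param phase Phase name (see [lookup_params()]).
#' @param session_time_min Session minute, `0 <= t < 60`.
#' @param n Number of types to draw.
#' @return Character vector of length `n`.
#' @export
sample_trial_type <- function(phase, session_time_min, n = 1) {
  check_phase(phase)
  if (phase == "Shaping") return(rep("shaping", n))
  if (phase == "ThresholdDetection") {
    if (session_time_min < 20) {
      return(sample(c("naive_anchor", "catch"), n, replace = TRUE,
                    prob = c(0.5, 0.5)))
    }
    return(sample(c("naive_anchor", "dynamic", "catch"), n, replace = TRUE,
                  prob = c(1, 1, 1) / 3))
  }
  p <- lookup_params(phase, session_time_min)$stimulus_probability
  sample(c("stimulus", "catch"), n, replace = TRUE, prob = c(p, 1 - p))
}

#' Staircase step size at a session minute
#'
#' Returns the dynamic-intensity step for the covering [step_schedule()]
#' segment. With `jitter = TRUE` the step is drawn uniformly from
#' `[central - halfwidth, central + halfwidth]`; with `jitter = FALSE` the
#' central value is returned (deterministic, for hand-traceable tests).
#' The first 20 minutes carry no step variation and raise a classed error
#' (`gonogo_no_variation`).
#'
#' @param session_time_min Session minute (must be >= 20).
#' @param modality `"icms"` (nC/ph) or `"auditory"` (percent amplitude).
#' @param jitter Logical; draw uniform jitter around the central step.
#' @return Step size in the modality's intensity units.
#' @examples
#' step_size(35, "icms", jitter = FALSE) # 0.60
#' @export
step_size <- function(session_time_min, modality = c("icms", "auditory"),
                      jitter = TRUE) {
  modality <- match.arg(modality)
  if (session_time_min < 20) {
    stop(structure(
      class = c("gonogo_no_variation", "error", "condition"),
      list(message = "no step variation before session minute 20",
           call = sys.call(-1))))
  }
  if (session_time_min >= 60) {
    stop("session_time_min outside the 1-h session", call. = FALSE)
  }
  sched <- step_schedule()
  m <- floor(session_time_min)
  row <- sched[sched$modality == modality & sched$start_min <= m &
                 m <= sched$end_min, , drop = FALSE]
  if (jitter) {
    stats::runif(1, row$central_step - row$halfwidth,
                 row$central_step + row$halfwidth)
  } else {
    row$central_step
  }
}
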