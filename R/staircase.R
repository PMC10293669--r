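#' Initialize the modified up/down staircase
#'
#' The threshold-detection task tracks one dynamic intensity per session,
#' started at the naive perception threshold (the "maximum"): 3--4 nC/ph
#' for ICMS animals, 100% amplitude for the auditory group.
#'
#' @param naive_intensity The anchor intensity (> 0).
#' @return An object of class `staircase_state` with fields
#'   `dynamic_intensity`, `naive_intensity`, and `history` (a data.frame of
#'   minute, presented intensity, outcome, and post-update intensity).
#' @examples
#' init_staircase(3)$dynamic_intensity # 3
#' @export
init_staircase <- function(naive_intensity) {
  if (!is.numeric(naive_intensity) || naive_intensity <= 0) {
    stop("naive_intensity must be > 0", call. = FALSE)
  }
  structure(
    list(dynamic_intensity = naive_intensity,
         naive_intensity = naive_intensity,
         history = data.frame(minute = numeric(0), intensity = numeric(0),
                              outcome = character(0), updated = numeric(0),
                              stringsAsFactors = FALSE)),
    class = "staircase_state"
  )
}

#' Step the staircase after a dynamic trial
#'
#' A hit on the dynamic intensity lowers it by the scheduled step size; a
#' miss raises it. The result is clamped to `[0, naive_intensity]` -- the
#' staircase never exceeds its anchor nor goes negative; a drawn step
#' larger than the remaining headroom saturates at the clamp. Only
#' dynamic-trial outcomes move the staircase (anchor and catch trials do
#' not), and no variation is applied before session minute 20, where the
#' staircase is frozen at the anchor.
#'
#' @param state A `staircase_state`.
#' @param outcome `"hit"` or `"miss"` from a dynamic trial.
#' @param session_time_min Session minute of the trial.
#' @param modality `"icms"` or `"auditory"` (selects the step schedule).
#' @param jitter Logical; uniform jitter around the central step.
#' @return The updated `staircase_state`.
#' @examples
#' s <- init_staircase(3)
#' staircase_update(s, "hit", 25, "icms", jitter = FALSE)$dynamic_intensity # 2
#' @export
staircase_update <- function(state, outcome, session_time_min,
                             modality = c("icms", "auditory"), jitter = TRUE) {
  stopifnot(inherits(state, "staircase_state"))
  modality <- match.arg(modality)
  if (!outcome %in% c("hit", "miss")) {
    stop("staircase updates come from dynamic trials only: outcome must be ",
         "'hit' or 'miss'", call. = FALSE)
  }
  presented <- state$dynamic_intensity
  if (session_time_min >= 20) {
    step <- step_size(session_time_min, modality, jitter = jitter)
    delta <- if (outcome == "hit") -step else step
    state$dynamic_intensity <-
      min(max(presented + delta, 0), state$naive_intensity)
  }
  state$history <- rbind(
    state$history,
    data.frame(minute = session_time_min, intensity = presented,
               outcome = outcome, updated = state$dynamic_intensity,
               stringsAsFactors = FALSE)
  )
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("Staircase: dynamic = %g (anchor %g), %d dynamic trials\n",
              x$dynamic_intensity, x$naive_intensity, nrow(x$history)))
  invisible(x)
}

#' Staircase trajectory as a data.frame
#'
#' Convenience accessor for exporting or plotting the staircase path
#' (time, presented intensity, outcome), as in a threshold-session
#' trajectory plot.
#'
#' @param state A `staircase_state`.
#' @return The `history` data.frame.
#' @export
staircase_trajectory <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  state$history
}
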