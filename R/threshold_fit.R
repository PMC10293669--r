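#' Bin dynamic-trial responses into quantal dose-response points
#'
#' Transforms per-trial hit/miss outcomes into percent hit rate per
#' intensity bin. Bins are half-open `[k*w, (k+1)*w)` with the bin center
#' as the dose label; empty bins are omitted. Only dynamic staircase
#' trials belong here -- anchor (naive-threshold) and catch trials are
#' excluded upstream -- and distracted trials are dropped.
#'
#' @param trials A data.frame with columns `intensity_value` and `outcome`
#'   (`"hit"`/`"miss"`); optional `trial_type` (filtered to `"dynamic"`
#'   when present) and `distracted`.
#' @param bin_width Bin width in intensity units: 0.5 nC/ph for ICMS,
#'   1 (percent amplitude) for auditory.
#' @return A data.frame with `dose`, `hit_rate_percent`, `n_trials`,
#'   ordered by dose.
#' @examples
#' tr <- data.frame(intensity_value = c(0.6, 0.7, 0.9),
#'                  outcome = c("hit", "hit", "miss"))
#' bin_responses(tr, 0.5) # one point: dose 0.75, 66.7%, n = 3
#' @export
bin_responses <- function(trials, bin_width = 0.5) {
  stopifnot(is.data.frame(trials), bin_width > 0)
  if ("trial_type" %in% names(trials)) {
    trials <- trials[trials$trial_type == "dynamic", ]
  }
  if ("distracted" %in% names(trials)) trials <- trials[!trials$distracted, ]
  trials <- trials[trials$outcome %in% c("hit", "miss"), ]
  if (!nrow(trials)) {
    stop("no dynamic trials to bin", call. = FALSE)
  }
  idx <- floor(trials$intensity_value / bin_width + 1e-9)
  agg <- tapply(trials$outcome == "hit", idx, function(z) c(sum(z), length(z)))
  k <- as.numeric(names(agg))
  out <- data.frame(
    dose = (k + 0.5) * bin_width,
    hit_rate_percent = 100 * vapply(agg, `[`, 0, 1) / vapply(agg, `[`, 0, 2),
    n_trials = as.integer(vapply(agg, `[`, 0, 2))
  )
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Residuals of the shared-slope Hill model over all sessions.
# theta = c(log_slope, log_ed50_1, ..., log_ed50_k)
hill_joint_residuals <- function(theta, points_by_session) {
  s <- exp(theta[1])
  unlist(lapply(seq_along(points_by_session), function(j) {
    pts <- points_by_session[[j]]
    ed50 <- exp(theta[1 + j])
    r <- exp(s * (log(pts$dose) - log(ed50)))
    pts$hit_rate_percent - 100 * r / (1 + r)
  }))
}

#' Joint quantal dose-response fit with a shared Hill slope
#'
#' Fits `y = 100 * x^s / (ED50^s + x^s)` to binned percent hit rates by
#' unweighted least squares, jointly over sessions: one ED50 per session
#' and a single Hill slope shared across all sessions of an animal. ED50
#' is constrained positive via a log transform; the slope is bounded to
#' `[0.1, 20]`. The optimizer is bounded Levenberg-Marquardt with
#' multi-start over slope and ED50 initial values (relative tolerance
#' 1e-8), keeping the best sum of squares.
#'
#' Sessions whose points are all at 0% or all at 100% (or with a single
#' dose) carry no information about their ED50; they are dropped with a
#' warning. At least two distinct doses must remain overall.
#'
#' @param points_by_session A list of dose-response data.frames (from
#'   [bin_responses()]), one per session; a single data.frame is treated
#'   as one session.
#' @return An object of class `psychometric_fit`: `ed50` (per retained
#'   session), `hillslope`, `threshold_mean`, `threshold_se` (mean and
#'   standard error of the session ED50s), `sse`, `dropped_sessions`,
#'   and `points` (the input, for re-fitting or plotting).
#' @export
fit_quantal <- function(points_by_session) {
  if (is.data.frame(points_by_session)) {
    points_by_session <- list(points_by_session)
  }
  stopifnot(length(points_by_session) >= 1)
  informative <- vapply(points_by_session, function(p) {
    length(unique(p$dose)) >= 2 &&
      any(p$hit_rate_percent > 0) && any(p$hit_rate_percent < 100)
  }, TRUE)
  dropped <- which(!informative)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " non-identifiable session(s) (degenerate dose-response data)",
            call. = FALSE)
  }
  pts <- points_by_session[informative]
  if (!length(pts)) {
    stop("no identifiable sessions: all dose-response data are degenerate",
         call. = FALSE)
  }
  k <- length(pts)
  doses <- unlist(lapply(pts, `[[`, "dose"))
  if (length(unique(doses)) < 2) {
    stop("need at least two distinct doses to fit", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)

  lower <- c(log(0.1), rep(log(min(doses)) - 5, k))
  upper <- c(log(20), rep(log(max(doses)) + 5, k))
  ed50_starts <- exp(seq(log(min(doses)), log(max(doses)), length.out = 3))
  best <- NULL
  for (s0 in c(0.5, 2, 8)) {
    for (e0 in ed50_starts) {
      theta0 <- c(log(s0), rep(log(e0), k))
      fit <- try(minpack.lm::nls.lm(
        par = theta0, lower = lower, upper = upper,
        fn = hill_joint_residuals, points_by_session = pts,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 500)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(theta = fit$par, sse = sse)
      }
    }
  }
  if (is.null(best)) stop("quantal fit failed to converge", call. = FALSE)
  ed50 <- exp(best$theta[-1])
  names(ed50) <- paste0("session_", which(informative))
  structure(
    list(ed50 = ed50,
         hillslope = exp(best$theta[1]),
         threshold_mean = mean(ed50),
         threshold_se = if (k > 1) stats::sd(ed50) / sqrt(k) else NA_real_,
         sse = best$sse,
         dropped_sessions = dropped,
         points = pts),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Quantal dose-response fit: %d session(s), shared Hill slope %.3f\n",
              length(x$ed50), x$hillslope))
  cat("  per-session ED50:", paste(sprintf("%.3f", x$ed50), collapse = ", "), "\n")
  cat(sprintf("  perception threshold: %.3f +/- %.3f (mean +/- SEM)\n",
              x$threshold_mean, x$threshold_se))
  invisible(x)
}

#' Predicted percent response of a fitted (or specified) Hill curve
#'
#' @param dose Dose(s) at which to evaluate.
#' @param ed50 ED50 of the curve.
#' @param hillslope Hill slope.
#' @return Percent response in `[0, 100]`.
#' @export
hill_response <- function(dose, ed50, hillslope) {
  r <- (dose / ed50)^hillslope
  ifelse(dose == 0, 0, 100 * r / (1 + r))
}

#' Estimate an animal's perception threshold from threshold sessions
#'
#' The full estimation path: per session, dynamic staircase trials are
#' binned into quantal dose-response points ([bin_responses()]); the Hill
#' curve is then fitted jointly across sessions with a shared slope
#' ([fit_quantal()]); the animal's perception threshold is the mean of the
#' session ED50s with its standard error. Five threshold sessions per
#' animal is the reference design.
#'
#' @param logs A `session_log` or list of them (ThresholdDetection phase),
#'   or a list of trial data.frames.
#' @param bin_width Bin width; defaults to 0.5 nC/ph for ICMS logs and 1%
#'   amplitude for auditory logs.
#' @return A `psychometric_fit` (see [fit_quantal()]).
#' @export
estimate_threshold <- function(logs, bin_width = NULL) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  stopifnot(length(logs) >= 1)
  get_trials <- function(x) if (inherits(x, "session_log")) x$trials else x
  if (is.null(bin_width)) {
    modality <- "icms"
    if (inherits(logs[[1]], "session_log") &&
        !is.null(logs[[1]]$config$modality)) {
      modality <- logs[[1]]$config$modality
    }
    bin_width <- if (modality == "icms") 0.5 else 1
  }
  pts <- lapply(logs, function(x) bin_responses(get_trials(x), bin_width))
  fit_quantal(pts)
}
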