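#' Confusion counts from a trial table
#'
#' Tallies hits, misses, false alarms and correct rejections from trial
#' records. Trials annotated as distracted are excluded before counting,
#' mirroring the online annotation plus offline validation used to remove
#' grooming/turned-away trials from analysis.
#'
#' @param trials A trial data.frame with at least `outcome` and
#'   `distracted` columns (as produced by [run_session()]); Shaping trials
#'   are ignored.
#' @return An object of class `confusion_counts`: a list with `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`.
#' @export
confusion_counts <- function(trials) {
  stopifnot(is.data.frame(trials), "outcome" %in% names(trials))
  if ("distracted" %in% names(trials)) trials <- trials[!trials$distracted, ]
  if ("trial_type" %in% names(trials)) {
    trials <- trials[trials$trial_type != "shaping", ]
  }
  new_counts(sum(trials$outcome == "hit"),
             sum(trials$outcome == "miss"),
             sum(trials$outcome == "false_alarm"),
             sum(trials$outcome == "correct_rejection"))
}

#' Construct confusion counts directly
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts
#'   (halves allowed after zero-count correction).
#' @return An object of class `confusion_counts`.
#' @export
new_counts <- function(hits, misses, false_alarms, correct_rejections) {
  x <- list(hits = hits, misses = misses, false_alarms = false_alarms,
            correct_rejections = correct_rejections)
  if (any(unlist(x) < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(x, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: H %g, M %g, FA %g, CR %g\n",
              x$hits, x$misses, x$false_alarms, x$correct_rejections))
  invisible(x)
}

#' Paired zero-count correction
#'
#' Any zero cell would put a 0 or 1 into the rate denominators and push
#' d-prime to infinity. The adjustment moves 0.5 from the non-zero member
#' of a pair (hits/misses; false alarms/correct rejections) to its zero
#' member, preserving the pair sum: a session with 119 hits and 0 misses
#' becomes 118.5 hits and 0.5 misses. Pairs without a zero are untouched.
#'
#' @param counts A `confusion_counts` of raw integer counts.
#' @return Adjusted `confusion_counts` with every cell > 0.
#' @examples
#' zero_correct(new_counts(119, 0, 30, 40))
#' @export
zero_correct <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  fix_pair <- function(a, b, what) {
    if (a == 0 && b == 0) {
      stop("no ", what, " trials in the session: both pair members are zero",
           call. = FALSE)
    }
    if (a == 0) c(0.5, b - 0.5) else if (b == 0) c(a - 0.5, 0.5) else c(a, b)
  }
  hm <- fix_pair(counts$hits, counts$misses, "stimulus")
  fc <- fix_pair(counts$false_alarms, counts$correct_rejections, "catch")
  new_counts(hm[1], hm[2], fc[1], fc[2])
}

#' Signal-detection performance scores
#'
#' The six per-session performance metrics of the go/no-go task:
#' \describe{
#'   \item{accuracy}{(H + CR) / (H + M + FA + CR)}
#'   \item{precision}{H / (H + FA)}
#'   \item{hit_rate}{H / (H + M)}
#'   \item{correct_rejection_rate}{CR / (CR + FA)}
#'   \item{f1}{harmonic mean of precision and hit rate}
#'   \item{d_prime}{z(hit rate) - z(false-alarm rate)}
#' }
#' Counts should be zero-corrected first (see [zero_correct()]) so that no
#' denominator vanishes and no rate sits at 0 or 1.
#'
#' @param counts A `confusion_counts` (apply [zero_correct()] first when
#'   raw counts may contain zeros).
#' @return A list of class `performance_scores` with the six fields plus
#'   `false_alarm_rate`.
#' @export
performance_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  h <- counts$hits; m <- counts$misses
  fa <- counts$false_alarms; cr <- counts$correct_rejections
  if (h + m == 0 || cr + fa == 0 || h + fa == 0) {
    stop("empty denominator; zero-correct the counts first", call. = FALSE)
  }
  precision <- h / (h + fa)
  hit_rate <- h / (h + m)
  fa_rate <- fa / (fa + cr)
  structure(
    list(accuracy = (h + cr) / (h + m + fa + cr),
         precision = precision,
         hit_rate = hit_rate,
         correct_rejection_rate = cr / (cr + fa),
         false_alarm_rate = fa_rate,
         f1 = 2 * precision * hit_rate / (precision + hit_rate),
         d_prime = if (hit_rate > 0 && hit_rate < 1 && fa_rate > 0 && fa_rate < 1)
           d_prime(hit_rate, fa_rate) else NA_real_),
    class = "performance_scores"
  )
}

#' @export
print.performance_scores <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.3f | precision %.3f | hit rate %.3f | ",
                     "CR rate %.3f | F1 %.3f | d' %.3f\n"),
              x$accuracy, x$precision, x$hit_rate,
              x$correct_rejection_rate, x$f1, x$d_prime))
  invisible(x)
}

#' Sensitivity index d-prime
#'
#' `d' = z(hit_rate) - z(false_alarm_rate)` with `z` the standard-normal
#' quantile function: the separation, in noise standard deviations,
#' between the signal and noise distributions implied by the two rates.
#'
#' @param hit_rate Hit rate strictly in (0, 1).
#' @param false_alarm_rate False-alarm rate `FA / (FA + CR)`, strictly in
#'   (0, 1).
#' @return d-prime.
#' @examples
#' d_prime(0.9, 0.1) # 2 * qnorm(0.9)
#' @export
d_prime <- function(hit_rate, false_alarm_rate) {
  if (any(c(hit_rate, false_alarm_rate) <= 0) ||
      any(c(hit_rate, false_alarm_rate) >= 1)) {
    stop("rates must lie strictly in (0, 1); apply the zero-count ",
         "correction to the counts first", call. = FALSE)
  }
  stats::qnorm(hit_rate) - stats::qnorm(false_alarm_rate)
}

#' Tier proficiency gates
#'
#' Evaluates whether a session history passes a training tier:
#' \describe{
#'   \item{Shaping}{>= 100 reward pellets with zero manual dispenses, in
#'     two consecutive sessions.}
#'   \item{Shape2Detect}{accuracy, precision and hit rate all >= 0.75 and
#'     >= 100 pellets, in two consecutive sessions.}
#'   \item{Detection}{accuracy, precision, hit rate, correct-rejection
#'     rate and F1 all >= 0.75 with d' >= 1.5, in three total (not
#'     necessarily consecutive) sessions.}
#' }
#'
#' @param tier `"Shaping"`, `"Shape2Detect"` or `"Detection"`.
#' @param sessions A data.frame, one row per session in chronological
#'   order. Columns used: `pellets`, `manual_dispenses` (Shaping,
#'   Shape2Detect); `accuracy`, `precision`, `hit_rate` (Shape2Detect,
#'   Detection); plus `correct_rejection_rate`, `f1`, `d_prime`
#'   (Detection).
#' @return A list: `pass` (logical) and `reasons` (character; criteria
#'   failing in the most recent session, or `"consecutive"` /
#'   `"sessions"` when only the session-count requirement is unmet).
#' @export
proficiency <- function(tier, sessions) {
  if (!tier %in% c("Shaping", "Shape2Detect", "Detection")) {
    stop("unknown tier: ", tier, call. = FALSE)
  }
  stopifnot(is.data.frame(sessions))
  crit <- switch(
    tier,
    Shaping = list(pellets = function(s) s$pellets >= 100,
                   manual_dispenses = function(s) s$manual_dispenses == 0),
    Shape2Detect = list(accuracy = function(s) s$accuracy >= 0.75,
                        precision = function(s) s$precision >= 0.75,
                        hit_rate = function(s) s$hit_rate >= 0.75,
                        pellets = function(s) s$pellets >= 100),
    Detection = list(accuracy = function(s) s$accuracy >= 0.75,
                     precision = function(s) s$precision >= 0.75,
                     hit_rate = function(s) s$hit_rate >= 0.75,
                     correct_rejection_rate = function(s) s$correct_rejection_rate >= 0.75,
                     f1 = function(s) s$f1 >= 0.75,
                     d_prime = function(s) s$d_prime >= 1.5)
  )
  ok <- vapply(seq_len(nrow(sessions)), function(i) {
    all(vapply(crit, function(f) isTRUE(f(sessions[i, , drop = FALSE])), TRUE))
  }, TRUE)
  if (tier == "Detection") {
    pass <- sum(ok) >= 3
    reasons <- if (pass) character(0) else if (nrow(sessions) && !ok[length(ok)]) {
      names(crit)[!vapply(crit, function(f)
        isTRUE(f(sessions[nrow(sessions), , drop = FALSE])), TRUE)]
    } else "sessions"
  } else {
    consec <- length(ok) >= 2 && any(ok[-length(ok)] & ok[-1])
    pass <- consec
    reasons <- if (pass) {
      character(0)
    } else if (nrow(sessions) && !ok[length(ok)]) {
      names(crit)[!vapply(crit, function(f)
        isTRUE(f(sessions[nrow(sessions), , drop = FALSE])), TRUE)]
    } else {
      "consecutive"
    }
  }
  list(pass = pass, reasons = reasons)
}

#' Pooled confusion matrix across sessions
#'
#' Builds the presented-trial-by-response table used to summarize baseline
#' accuracy sessions: rows are the presented trial type (stimulus, catch),
#' columns the response (poke, no poke).
#'
#' @param trials A trial data.frame, or a list of `session_log`s /
#'   trial data.frames to pool.
#' @return A 2x2 integer matrix.
#' @export
pooled_confusion <- function(trials) {
  if (inherits(trials, "session_log")) trials <- trials$trials
  if (is.list(trials) && !is.data.frame(trials)) {
    trials <- do.call(rbind, lapply(trials, function(x) {
      df <- if (inherits(x, "session_log")) x$trials else x
      df[, c("trial_type", "outcome", "distracted")]
    }))
  }
  cc <- confusion_counts(trials)
  matrix(c(cc$hits, cc$misses, cc$false_alarms, cc$correct_rejections),
         nrow = 2, byrow = TRUE,
         dimnames = list(presented = c("stimulus", "catch"),
                         response = c("poke", "no_poke")))
}

#' Per-session score table for one or more logs
#'
#' Convenience wrapper: confusion counts (with zero-count correction) and
#' [performance_scores()] per session, one row each.
#'
#' @param logs A `session_log` or list of them.
#' @return A data.frame of counts, scores and pellets per session.
#' @export
session_scores <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  rows <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    cc <- zero_correct(confusion_counts(log$trials))
    sc <- performance_scores(cc)
    data.frame(session = i, seed = log$seed,
               hits = cc$hits, misses = cc$misses,
               false_alarms = cc$false_alarms,
               correct_rejections = cc$correct_rejections,
               accuracy = sc$accuracy, precision = sc$precision,
               hit_rate = sc$hit_rate,
               correct_rejection_rate = sc$correct_rejection_rate,
               f1 = sc$f1, d_prime = sc$d_prime,
               pellets = log$pellets,
               manual_dispenses = log$manual_dispenses)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
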