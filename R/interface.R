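trial_csv_columns <- c("trial_index", "phase", "minute", "trial_type",
                       "intensity_value", "intensity_units", "outcome",
                       "first_poke_ms", "punished", "timeout_s",
                       "n_airpuffs", "distracted", "trial_start_ms")

#' Write a session log to disk
#'
#' Serializes a [run_session()] log as two plain-text files: a per-trial
#' CSV (columns: trial_index, phase, minute, trial_type, intensity_value,
#' intensity_units, outcome, first_poke_ms, punished, timeout_s,
#' n_airpuffs, distracted, trial_start_ms) and a JSON-lines event file --
#' one JSON object per line, the first being a header carrying the
#' configuration, seed and observer ground truth, followed by timestamped
#' events (pokes, pellets, air puffs, timeouts, pauses) including the full
#' per-trial poke times.
#'
#' @param log A `session_log`.
#' @param trials_path Path for the trial CSV.
#' @param events_path Path for the JSON-lines event log; defaults to the
#'   trial path with a `.jsonl` extension.
#' @return Invisibly, the two paths.
#' @export
write_session_log <- function(log, trials_path,
                              events_path = sub("\\.csv$", ".jsonl", trials_path)) {
  stopifnot(inherits(log, "session_log"))
  df <- log$trials[, trial_csv_columns, drop = FALSE]
  utils::write.csv(df, trials_path, row.names = FALSE)
  header <- list(
    record = "header",
    seed = log$seed,
    pellets = log$pellets,
    manual_dispenses = log$manual_dispenses,
    config = unclass(log$config),
    observer = unclass(log$observer),
    poke_times_ms = unname(lapply(log$trials$poke_times_ms, as.numeric))
  )
  con <- file(events_path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  if (nrow(log$events)) {
    for (i in seq_len(nrow(log$events))) {
      writeLines(jsonlite::toJSON(
        list(record = "event", t_ms = log$events$t_ms[i],
             kind = log$events$kind[i],
             trial_index = log$events$trial_index[i]),
        auto_unbox = TRUE, na = "null", digits = NA), con)
    }
  }
  invisible(c(trials = trials_path, events = events_path))
}

#' Read a session log back from disk
#'
#' Inverse of [write_session_log()]: reconstructs the `session_log`
#' (config, seed, observer ground truth, trials with poke times, events)
#' so that `write` then `read` is the identity on all fields.
#'
#' @param trials_path Path to the trial CSV.
#' @param events_path Path to the JSON-lines event log; when missing, the
#'   log is reconstructed from the CSV alone (no events, no config).
#' @return A `session_log`.
#' @export
read_session_log <- function(trials_path,
                             events_path = sub("\\.csv$", ".jsonl", trials_path)) {
  df <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_csv_columns, names(df))
  if (length(missing_cols)) {
    stop("trial CSV ", trials_path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$punished <- as.logical(df$punished)
  df$distracted <- as.logical(df$distracted)
  config <- NULL; observer <- NULL; seed <- NA_integer_
  pellets <- sum(df$outcome == "hit"); manual <- 0L
  events <- data.frame(t_ms = numeric(0), kind = character(0),
                       trial_index = integer(0))
  df$poke_times_ms <- lapply(df$first_poke_ms, function(x)
    if (is.na(x)) numeric(0) else x)
  if (file.exists(events_path)) {
    lines <- readLines(events_path)
    recs <- lapply(lines, jsonlite::fromJSON)
    header <- recs[[1]]
    if (!identical(header$record, "header")) {
      stop("event log ", events_path, " line 1: expected a header record",
           call. = FALSE)
    }
    seed <- header$seed
    pellets <- header$pellets
    manual <- header$manual_dispenses
    config <- structure(header$config, class = "session_config")
    observer <- structure(header$observer, class = "observer_model")
    if (length(header$poke_times_ms) == nrow(df)) {
      df$poke_times_ms <- lapply(header$poke_times_ms, as.numeric)
    }
    ev <- recs[-1]
    if (length(ev)) {
      events <- data.frame(
        t_ms = vapply(ev, function(e) as.numeric(e$t_ms), 0),
        kind = vapply(ev, function(e) as.character(e$kind), ""),
        trial_index = vapply(ev, function(e)
          if (is.null(e$trial_index)) NA_integer_ else as.integer(e$trial_index),
          0L))
    }
  }
  structure(
    list(config = config, observer = observer, seed = seed,
         trials = df, events = events, pellets = pellets,
         manual_dispenses = manual, staircase = NULL),
    class = "session_log"
  )
}

#' Default run configuration
#'
#' The configuration shipped with the package: session schedules and
#' stimulus parameters reproducing the published task (Shape2Detect and
#' step-size tables, Detection constants, ICMS pulse train and tone
#' specs), plus default observer parameters.
#'
#' @return A nested list suitable for [write_run_config()].
#' @export
default_run_config <- function() {
  list(
    session = list(phase = "Detection", modality = "icms",
                   naive_intensity = 3, seed = 1, session_minutes = 60,
                   jitter = TRUE),
    pulse_train = unclass(pulse_train_spec()),
    tone = unclass(tone_spec()),
    observer = unclass(observer_model(true_ed50 = 1.6))
  )
}

#' Write / read a run configuration (YAML)
#'
#' @param config A nested configuration list (see [default_run_config()]).
#' @param path File path.
#' @return `read_run_config()` returns the configuration list, with
#'   defaults filled in for omitted keys.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (section in names(base)) {
    if (is.null(cfg[[section]])) {
      cfg[[section]] <- base[[section]]
    } else {
      miss <- setdiff(names(base[[section]]), names(cfg[[section]]))
      cfg[[section]][miss] <- base[[section]][miss]
    }
  }
  cfg
}

config_to_session <- function(cfg) {
  s <- cfg$session
  session_config(phase = s$phase, modality = s$modality,
                 naive_intensity = s$naive_intensity, seed = s$seed,
                 session_minutes = s$session_minutes, jitter = s$jitter)
}

config_to_observer <- function(cfg) {
  do.call(observer_model, cfg$observer)
}

cli_usage <- function() {
  paste(
    "usage: gonogo <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate --phase <P> --modality <M> --seed <n> --sessions <k> --out-dir <dir>",
    "           [--config <yaml>] [--naive <intensity>] [--no-jitter]",
    "  metrics  --trials <csv> [<csv> ...] --out-dir <dir>",
    "  fit      --trials <csv> [<csv> ...] --out <report.json>",
    "           [--dose-response <csv>] [--bin-width <w>]",
    "  report   --trials <csv> [<csv> ...]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list(trials = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    take <- function() { i <<- i + 1; args[[i]] }
    switch(a,
      "--phase" = { opts$phase <- take() },
      "--modality" = { opts$modality <- take() },
      "--seed" = { opts$seed <- as.integer(take()) },
      "--sessions" = { opts$sessions <- as.integer(take()) },
      "--out-dir" = { opts$out_dir <- take() },
      "--out" = { opts$out <- take() },
      "--config" = { opts$config <- take() },
      "--naive" = { opts$naive <- as.numeric(take()) },
      "--bin-width" = { opts$bin_width <- as.numeric(take()) },
      "--dose-response" = { opts$dose_response <- take() },
      "--no-jitter" = { opts$jitter <- FALSE },
      "--trials" = {
        while (i < length(args) && !startsWith(args[[i + 1]], "--")) {
          i <- i + 1
          opts$trials <- c(opts$trials, args[[i]])
        }
      },
      stop("unknown option: ", a, call. = FALSE)
    )
    i <- i + 1
  }
  opts
}

#' Command-line entry point
#'
#' Drives the pipeline from a shell (see `inst/cli/gonogo.R` for the
#' installed wrapper script): `simulate` runs sessions and writes trial
#' CSVs + event logs; `metrics` writes per-session score tables and a
#' pooled confusion matrix; `fit` writes a threshold report (JSON) and a
#' dose-response table; `report` prints a human-readable summary.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
gonogo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) ||
      !args[[1]] %in% c("simulate", "metrics", "fit", "report")) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[[1]]
  opts <- tryCatch(parse_cli_args(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", cli_usage())
    return(invisible(1L))
  }
  status <- tryCatch({
    switch(sub,
           simulate = cli_simulate(opts),
           metrics = cli_metrics(opts),
           fit = cli_fit(opts),
           report = cli_report(opts))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else default_run_config()
  if (!is.null(opts$phase)) cfg$session$phase <- opts$phase
  if (!is.null(opts$modality)) cfg$session$modality <- opts$modality
  if (!is.null(opts$seed)) cfg$session$seed <- opts$seed
  if (!is.null(opts$naive)) cfg$session$naive_intensity <- opts$naive
  if (!is.null(opts$jitter)) cfg$session$jitter <- opts$jitter
  n_sessions <- if (!is.null(opts$sessions)) opts$sessions else 1L
  out_dir <- if (!is.null(opts$out_dir)) opts$out_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  observer <- config_to_observer(cfg)
  for (k in seq_len(n_sessions)) {
    scfg <- config_to_session(cfg)
    scfg$seed <- as.integer(cfg$session$seed + k - 1L)
    log <- run_session(scfg, observer)
    base <- file.path(out_dir, sprintf("session_%s_seed%d", scfg$phase, scfg$seed))
    write_session_log(log, paste0(base, "_trials.csv"))
    message(sprintf("wrote %s_trials.csv (%d trials, %d pellets)",
                    base, nrow(log$trials), log$pellets))
  }
  invisible(NULL)
}

cli_load_logs <- function(opts) {
  if (!length(opts$trials)) stop("no --trials files given", call. = FALSE)
  lapply(opts$trials, read_session_log)
}

cli_metrics <- function(opts) {
  logs <- cli_load_logs(opts)
  out_dir <- if (!is.null(opts$out_dir)) opts$out_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scores <- session_scores(logs)
  utils::write.csv(scores, file.path(out_dir, "session_scores.csv"),
                   row.names = FALSE)
  cm <- pooled_confusion(logs)
  cm_df <- data.frame(presented = rownames(cm), poke = cm[, "poke"],
                      no_poke = cm[, "no_poke"], row.names = NULL)
  utils::write.csv(cm_df, file.path(out_dir, "pooled_confusion.csv"),
                   row.names = FALSE)
  message("wrote session_scores.csv and pooled_confusion.csv to ", out_dir)
  invisible(NULL)
}

cli_fit <- function(opts) {
  logs <- cli_load_logs(opts)
  fit <- estimate_threshold(logs, bin_width = opts$bin_width)
  out <- if (!is.null(opts$out)) opts$out else "threshold_report.json"
  jsonlite::write_json(
    list(ed50_per_session = as.list(fit$ed50),
         shared_hillslope = fit$hillslope,
         threshold_mean = fit$threshold_mean,
         threshold_se = fit$threshold_se,
         dropped_sessions = fit$dropped_sessions),
    out, auto_unbox = TRUE, digits = NA)
  if (!is.null(opts$dose_response)) {
    dr <- do.call(rbind, lapply(seq_along(fit$points), function(j) {
      cbind(session = j, fit$points[[j]])
    }))
    utils::write.csv(dr, opts$dose_response, row.names = FALSE)
  }
  message(sprintf("threshold %.3f +/- %.3f (Hill slope %.3f); wrote %s",
                  fit$threshold_mean, fit$threshold_se, fit$hillslope, out))
  invisible(NULL)
}

cli_report <- function(opts) {
  logs <- cli_load_logs(opts)
  scores <- session_scores(logs)
  cat(sprintf("Sessions: %d\n", nrow(scores)))
  cat(sprintf("Mean accuracy: %.1f%%  hit rate: %.1f%%  CR rate: %.1f%%  d': %.2f\n",
              100 * mean(scores$accuracy), 100 * mean(scores$hit_rate),
              100 * mean(scores$correct_rejection_rate),
              mean(scores$d_prime)))
  for (tier in c("Shaping", "Shape2Detect", "Detection")) {
    prof <- proficiency(tier, scores)
    cat(sprintf("%s gate: %s%s\n", tier,
                if (prof$pass) "PASS" else "fail",
                if (length(prof$reasons))
                  paste0(" (", paste(prof$reasons, collapse = ", "), ")")
                else ""))
  }
  has_dynamic <- any(vapply(logs, function(l)
    any(l$trials$trial_type == "dynamic"), TRUE))
  if (has_dynamic) {
    fit <- estimate_threshold(logs, bin_width = opts$bin_width)
    cat(sprintf("Perception threshold: %.3f +/- %.3f (shared Hill slope %.3f)\n",
                fit$threshold_mean, fit$threshold_se, fit$hillslope))
  }
  invisible(NULL)
}
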