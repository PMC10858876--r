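# End-to-end orchestration: simulate (or load) a cohort, quantify each
# session's seizure power, after-discharge and photometry activity, assemble
# the design matrix, and run the correlation and contribution analyses.

#' Analyze one session (EEG + photometry)
#'
#' Filters the EEG, detects the after-discharge and measures the 30-s
#' seizure band power, corrects the photometry and summarizes pre- and
#' during-seizure activity. The during-seizure window uses the detected
#' ictal duration, falling back to the stimulation window when no
#' after-discharge was detected.
#'
#' @param eeg An [eeg_recording] with a stimulation event.
#' @param photometry A [photometry_recording].
#' @param induction_s Induction time, s; defaults to the first EEG event
#'   onset.
#' @param stim_duration_s Stimulation-train length, s (default 10).
#' @param band Analysis band, Hz (default `c(4, 14)`).
#' @param k_sd,min_len_s,max_gap_s After-discharge detection parameters, see
#'   [detect_afterdischarge()].
#' @return List with `outcome` (`seizure_outcome`) and `activity`
#'   (`epoch_activity`).
#' @export
analyze_session <- function(eeg, photometry, induction_s = NULL,
                            stim_duration_s = 10, band = c(4, 14),
                            k_sd = 3, min_len_s = 2, max_gap_s = 2) {
  if (is.null(induction_s)) {
    if (!nrow(eeg$events)) {
      stop("argument error: no events and no `induction_s` given", call. = FALSE)
    }
    induction_s <- eeg$events$onset_s[1L]
  }
  filtered <- eeg_preprocess(eeg)
  outcome <- detect_afterdischarge(filtered, induction_s,
                                   stim_duration_s = stim_duration_s,
                                   k_sd = k_sd, min_len_s = min_len_s,
                                   max_gap_s = max_gap_s, band = band,
                                   preprocessed = TRUE)
  ct <- correct_photometry(photometry)
  act <- epoch_activity(ct, seizure_duration_s = outcome$duration_s,
                        stim_duration_s = stim_duration_s)
  list(outcome = outcome, activity = act)
}

#' Run the full peri-seizure experiment pipeline
#'
#' simulate -> per-session EEG and photometry analysis -> design matrix ->
#' correlations and bootstrap contribution analysis -> report. Sessions that
#' fail (e.g. degenerate baseline) are excluded with a logged reason, never
#' silently dropped. All randomness flows from the single configured seed.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized keys: `seed` (integer), `n_sessions` (>= 1), `simulation`
#'   (named overrides passed to [sim_config()]), `analysis` (`band`,
#'   `n_boot`, `train_fraction`, `k_sd`, `min_len_s`, `max_gap_s`),
#'   `output_dir` (optional; report JSON and CSV tables are written there).
#' @return An object of class `run_report`: `sessions` (per-session data
#'   frame), `correlations`, `contribution` (`contribution_result`),
#'   `exclusions`, `config`, `seed`, `version`, `timestamp`.
#' @export
run_experiment <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("invalid config: not a list or YAML path", call. = FALSE)
  seed <- cfg$seed %||% 1L
  check_scalar(seed, "seed")
  n_sessions <- cfg$n_sessions %||% 30
  if (!is.numeric(n_sessions) || length(n_sessions) != 1L || n_sessions < 1) {
    stop("invalid config: `n_sessions` must be >= 1", call. = FALSE)
  }
  sim_args <- cfg$simulation %||% list()
  scfg <- do.call(sim_config, sim_args)
  an <- cfg$analysis %||% list()
  band <- as.numeric(an$band %||% c(4, 14))
  n_boot <- an$n_boot %||% 5000
  train_fraction <- an$train_fraction %||% 0.7
  k_sd <- an$k_sd %||% 3; min_len_s <- an$min_len_s %||% 2
  max_gap_s <- an$max_gap_s %||% 2

  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[periseizure] ", line)
  }
  log_msg("simulating cohort: %d sessions, seed %d", n_sessions, as.integer(seed))
  cohort <- generate_cohort(scfg, n_sessions, seed)
  rows <- vector("list", n_sessions)
  exclusions <- list()
  for (i in seq_len(n_sessions)) {
    s <- cohort[[i]]
    res <- tryCatch(
      analyze_session(s$eeg, s$photometry,
                      induction_s = scfg$induction_time,
                      stim_duration_s = scfg$stim_duration, band = band,
                      k_sd = k_sd, min_len_s = min_len_s,
                      max_gap_s = max_gap_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        list(session = i, reason = conditionMessage(res))
      log_msg("session %d excluded: %s", i, conditionMessage(res))
      warning(sprintf("session %d excluded: %s", i, conditionMessage(res)),
              call. = FALSE)
      next
    }
    rows[[i]] <- data.frame(
      session = i,
      seed = s$seed,
      provoked = res$outcome$provoked,
      duration_s = res$outcome$duration_s,
      seizure_power = res$outcome$band_power,
      pre_mean = res$activity$pre_mean,
      during_mean = res$activity$during_mean,
      latent_pre = s$truth$latent_pre,
      latent_during = s$truth$latent_during,
      true_duration = s$truth$true_duration)
  }
  sessions <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sessions) || nrow(sessions) < 6L) {
    stop("pipeline error: fewer than 6 analyzable sessions", call. = FALSE)
  }
  log_msg("analyzed %d sessions (%d excluded)", nrow(sessions),
          length(exclusions))
  dm <- design_matrix(sessions$pre_mean, sessions$during_mean,
                      sessions$seizure_power, ids = sessions$session)
  log_msg("contribution analysis: n_boot = %d, train fraction %.2f",
          as.integer(n_boot), train_fraction)
  correlations <- list(
    pre_vs_power = correlate(sessions$pre_mean, sessions$seizure_power),
    during_vs_power = correlate(sessions$during_mean, sessions$seizure_power))
  contribution <- contribution_analysis(dm, n_boot = n_boot,
                                        train_fraction = train_fraction,
                                        seed = derive_seed(seed, 999983L))
  prob <- seizure_probability(sessions$provoked)
  report <- structure(list(
    sessions = sessions,
    seizure_probability = prob,
    correlations = correlations,
    contribution = contribution,
    exclusions = exclusions,
    config = list(seed = seed, n_sessions = n_sessions,
                  simulation = unclass(scfg),
                  analysis = list(band = band, n_boot = n_boot,
                                  train_fraction = train_fraction,
                                  k_sd = k_sd, min_len_s = min_len_s,
                                  max_gap_s = max_gap_s,
                                  detection = "automated threshold surrogate for visual scoring")),
    seed = as.integer(seed),
    version = as.character(utils::packageVersion("periseizure")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    log = log_lines),
    class = "run_report")
  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d sessions analyzed (%d excluded), seed %d\n",
              nrow(x$sessions), length(x$exclusions), x$seed))
  cat(sprintf("  seizure probability: %.1f%%\n",
              x$seizure_probability$percent_1dp))
  cat(sprintf("  r(pre, power)    = %+.3f (p = %.3g)\n",
              x$correlations$pre_vs_power$r, x$correlations$pre_vs_power$p_value))
  cat(sprintf("  r(during, power) = %+.3f (p = %.3g)\n",
              x$correlations$during_vs_power$r,
              x$correlations$during_vs_power$p_value))
  print(x$contribution)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `report.json` (everything except the per-session table),
#' `sessions.csv` and `run.log` into `out_dir`. JSON output is deterministic
#' given the report content apart from the `timestamp` field.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$sessions, file.path(out_dir, "sessions.csv"),
                   row.names = FALSE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  contrib <- report$contribution
  js <- list(
    seed = report$seed,
    version = report$version,
    timestamp = report$timestamp,
    n_sessions = nrow(report$sessions),
    exclusions = report$exclusions,
    seizure_probability = unclass(report$seizure_probability),
    correlations = report$correlations,
    contribution = list(
      r_squared_full = contrib$r_squared_full,
      contributions = as.list(contrib$contributions),
      relative_contributions = as.list(contrib$relative_contributions),
      coefficients = as.list(contrib$coefficients),
      n_boot = contrib$n_boot,
      train_fraction = contrib$train_fraction,
      seed = contrib$seed),
    config = report$config)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
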