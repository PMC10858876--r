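# Seizure-level and behavior-level summary metrics.

#' Detect a post-stimulation after-discharge and measure its duration
#'
#' Automated surrogate for the visual call of seizure-like after-discharges:
#' the 4-14 Hz band-power envelope is computed in consecutive 1-s epochs of
#' the filtered EEG, thresholded at `baseline mean + k_sd * baseline SD`
#' (baseline = the 60 s before induction), and supra-threshold runs after
#' stimulation offset are merged across gaps of at most `max_gap_s`. A
#' seizure is provoked iff a merged run starting within `onset_tol_s` of
#' stimulation offset lasts at least `min_len_s`; its whole span is the ictal
#' duration.
#'
#' @param rec An [eeg_recording] with at least 60 s before `induction_s`.
#' @param induction_s Stimulation-onset time, s.
#' @param stim_duration_s Stimulation-train length, s (default 10).
#' @param k_sd Threshold in baseline SDs above the baseline mean (default 3).
#' @param min_len_s Minimum event length, s (default 2).
#' @param max_gap_s Maximum sub-threshold gap merged into one event, s
#'   (default 2).
#' @param onset_tol_s Latest post-offset start of a provoked event, s
#'   (default 5).
#' @param band Frequency band, Hz (default `c(4, 14)`).
#' @param preprocessed Set TRUE if `rec` is already filtered.
#' @return An object of class `seizure_outcome`: `provoked`, `duration_s`,
#'   `band_power` (uV^2 over the 30-s post-induction window), `stim_hz`,
#'   plus the detection parameters (`threshold`, `k_sd`, `min_len_s`,
#'   `max_gap_s`) for provenance. The threshold rule is a surrogate for
#'   visual scoring and is labeled as such in pipeline reports.
#' @export
detect_afterdischarge <- function(rec, induction_s, stim_duration_s = 10,
                                  k_sd = 3, min_len_s = 2, max_gap_s = 2,
                                  onset_tol_s = 5, band = c(4, 14),
                                  preprocessed = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (induction_s < 60) {
    stop("window error: need >= 60 s of pre-induction baseline", call. = FALSE)
  }
  if (!preprocessed) rec <- eeg_preprocess(rec)
  dur <- length(rec$samples) / rec$fs
  offset_s <- induction_s + stim_duration_s
  # per-1-s-epoch band power, epochs aligned to stimulation offset
  epoch_power <- function(win) {
    est <- welch_psd(rec, win)
    apply(est$epoch_psd, 2L, function(p)
      band_integral(est$frequencies, p, band))
  }
  base_pow <- epoch_power(c(induction_s - 60, induction_s))
  n_post <- floor(dur - offset_s)
  if (n_post < 1L) {
    stop("window error: no post-stimulation samples", call. = FALSE)
  }
  post_pow <- epoch_power(c(offset_s, offset_s + n_post))
  thr <- mean(base_pow) + k_sd * stats::sd(base_pow)
  supra <- post_pow > thr
  runs <- merge_runs(supra, max_gap = as.integer(round(max_gap_s)))
  provoked <- FALSE; duration_s <- 0
  if (nrow(runs)) {
    # epoch k covers [offset + k - 1, offset + k); run start time rel. offset
    starts <- runs[, 1L] - 1L
    ok <- starts <= onset_tol_s & (runs[, 2L] - runs[, 1L] + 1L) >= min_len_s
    if (any(ok)) {
      r <- which(ok)[1L]
      provoked <- TRUE
      duration_s <- runs[r, 2L] - runs[r, 1L] + 1
    }
  }
  bp <- if (induction_s + 30 <= dur + 1e-9) {
    seizure_power(rec, induction_s, band = band, preprocessed = TRUE)$band_power
  } else NA_real_
  stim_hz <- if (nrow(rec$events)) rec$events$stim_hz[1L] else NA_real_
  structure(list(provoked = provoked, duration_s = duration_s,
                 band_power = bp, stim_hz = stim_hz,
                 threshold = thr, k_sd = k_sd, min_len_s = min_len_s,
                 max_gap_s = max_gap_s,
                 detection = "automated threshold surrogate for visual scoring"),
            class = "seizure_outcome")
}

# maximal TRUE runs of `x`, merging runs separated by <= max_gap FALSEs;
# returns a matrix with columns (start, end), 1-based inclusive
merge_runs <- function(x, max_gap = 0L) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs) || max_gap <= 0L) return(runs)
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1L) + 1L) {
    gap <- runs[i, 1L] - merged[nrow(merged), 2L] - 1L
    if (gap <= max_gap) {
      merged[nrow(merged), 2L] <- runs[i, 2L]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  merged
}

#' @export
print.seizure_outcome <- function(x, ...) {
  cat(sprintf("<seizure_outcome> provoked %s, duration %.1f s, band power %.4g uV^2 (stim %g Hz)\n",
              x$provoked, x$duration_s, x$band_power, x$stim_hz))
  invisible(x)
}

#' Seizure probability of a set of stimulations
#'
#' Provoked seizures divided by all stimulations, as a percentage.
#'
#' @param outcomes List of `seizure_outcome` objects, or a logical vector of
#'   provoked flags.
#' @return List of class `seizure_probability`: `percent` (exact),
#'   `percent_1dp` (one decimal), `percent_int` (nearest integer, half-up),
#'   `n_provoked`, `n_total`.
#' @export
seizure_probability <- function(outcomes) {
  provoked <- if (is.logical(outcomes)) outcomes else
    vapply(outcomes, function(o) isTRUE(o$provoked), logical(1))
  if (!length(provoked)) stop("argument error: empty outcome list", call. = FALSE)
  pct <- 100 * sum(provoked) / length(provoked)
  structure(list(percent = pct,
                 percent_1dp = round(pct, 1),
                 percent_int = floor(pct + 0.5),   # half-up
                 n_provoked = sum(provoked),
                 n_total = length(provoked)),
            class = "seizure_probability")
}

#' @export
print.seizure_probability <- function(x, ...) {
  cat(sprintf("<seizure_probability> %d/%d stimulations provoked a seizure: %.1f%% (%d%%)\n",
              x$n_provoked, x$n_total, x$percent_1dp, x$percent_int))
  invisible(x)
}

#' Sleep fragmentation index of one state
#'
#' A behavioral bout is a maximal run of 5-s epochs without transitions; the
#' fragmentation index of a state is its number of bouts divided by its
#' total number of epochs, between 1/n (one consolidated bout) and 1 (every
#' epoch isolated).
#'
#' @param h A [hypnogram].
#' @param state One of `"Wake"`, `"NREM"`, `"REM"`.
#' @return List of class `fragmentation_result`: `state`, `n_bouts`,
#'   `n_epochs`, `index` (NA with `defined = FALSE` when the state never
#'   occurs).
#' @export
fragmentation_index <- function(h, state) {
  stopifnot(inherits(h, "hypnogram"))
  state <- match.arg(state, c("Wake", "NREM", "REM"))
  r <- rle(h$states)
  n_bouts <- sum(r$values == state)
  n_epochs <- sum(r$lengths[r$values == state])
  if (n_epochs == 0L) {
    return(structure(list(state = state, n_bouts = 0L, n_epochs = 0L,
                          index = NA_real_, defined = FALSE),
                     class = "fragmentation_result"))
  }
  structure(list(state = state, n_bouts = n_bouts, n_epochs = n_epochs,
                 index = n_bouts / n_epochs, defined = TRUE),
            class = "fragmentation_result")
}

#' @export
print.fragmentation_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<fragmentation_result> %s: state absent, index undefined\n", x$state))
  } else {
    cat(sprintf("<fragmentation_result> %s: %d bouts / %d epochs = %.3f\n",
                x$state, x$n_bouts, x$n_epochs, x$index))
  }
  invisible(x)
}

#' Percentage of time per sleep state
#'
#' Per-state epoch percentages over a subset of epochs (e.g. the dark or
#' light phase, supplied as an index mask by the caller).
#'
#' @param h A [hypnogram].
#' @param phase_mask Logical vector over epochs, or integer epoch indices;
#'   default all epochs.
#' @return Named numeric vector of percentages (Wake, NREM, REM), summing
#'   to 100.
#' @export
state_percentages <- function(h, phase_mask = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$states)
  idx <- if (is.null(phase_mask)) seq_len(n)
  else if (is.logical(phase_mask)) which(phase_mask) else as.integer(phase_mask)
  if (!length(idx)) stop("argument error: empty phase mask", call. = FALSE)
  if (any(idx < 1L | idx > n)) {
    stop("argument error: phase mask outside the hypnogram", call. = FALSE)
  }
  tab <- table(factor(h$states[idx], levels = c("Wake", "NREM", "REM")))
  stats::setNames(100 * as.numeric(tab) / length(idx), names(tab))
}

#' Sucrose preference index
#'
#' Volume (or mass) of sucrose solution consumed divided by total liquid
#' consumed; 0.5 means no preference.
#'
#' @param sucrose_consumed Sucrose solution consumed (g or ml).
#' @param total_consumed Total liquid consumed, same units.
#' @return Preference index in `[0, 1]`.
#' @export
sucrose_preference <- function(sucrose_consumed, total_consumed) {
  check_scalar(total_consumed, "total_consumed", min = 0, strict_min = TRUE)
  check_scalar(sucrose_consumed, "sucrose_consumed", min = 0,
               max = total_consumed)
  sucrose_consumed / total_consumed
}
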