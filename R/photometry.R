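# Dual-excitation fiber-photometry correction.
#
# Pipeline (per recording): median-anchored linear bleach detrend over the
# 6-min analysis window centered on induction; z-score of each channel by the
# median and SD of its 60-s pre-induction baseline; motion correction by
# subtracting the z-scored isosbestic (405 nm) trace from the z-scored
# calcium-dependent (465 nm) trace.

#' Median-anchored linear detrend of a fluorescence trace
#'
#' Removes slow linear photobleaching: the straight line through
#' (center of first 50 s, median of first 50 s) and (center of last 50 s,
#' median of last 50 s) of the analysis window is subtracted. Median anchors
#' make the line insensitive to transients, unlike an ordinary least-squares
#' fit.
#'
#' @param time_s Time grid in seconds.
#' @param trace Raw fluorescence values (same length as `time_s`).
#' @param analysis_window Length-2 window `(start_s, end_s)` in seconds;
#'   values outside it are detrended with the same line.
#' @param flank_s Length of the two anchor flanks in seconds (default 50).
#' @return Numeric vector: `trace` minus the fitted line.
#' @export
detrend_linear <- function(time_s, trace, analysis_window, flank_s = 50) {
  stopifnot(length(time_s) == length(trace), length(analysis_window) == 2L)
  if (diff(analysis_window) < 2 * flank_s + 1e-9) {
    stop("window error: analysis window shorter than the two anchor flanks",
         call. = FALSE)
  }
  lo <- analysis_window[1L]; hi <- analysis_window[2L]
  in1 <- time_s >= lo & time_s < lo + flank_s
  in2 <- time_s >= hi - flank_s & time_s < hi
  if (sum(in1) < 2L || sum(in2) < 2L) {
    stop("window error: too few samples in a detrend flank", call. = FALSE)
  }
  # anchor abscissae at the median sample time of each flank, so an exactly
  # linear trace detrends to zero on any sample grid
  x1 <- stats::median(time_s[in1]); x2 <- stats::median(time_s[in2])
  y1 <- stats::median(trace[in1]); y2 <- stats::median(trace[in2])
  slope <- (y2 - y1) / (x2 - x1)
  trace - (y1 + slope * (time_s - x1))
}

#' Baseline z-score of a detrended trace
#'
#' Normalizes by the median and standard deviation of the 60 s immediately
#' preceding seizure induction: `z(t) = (x(t) - median_baseline) / sd_baseline`.
#'
#' @param time_s Time grid in seconds.
#' @param trace Detrended fluorescence values.
#' @param induction_s Seizure-induction time in seconds; at least
#'   `baseline_s` seconds of samples must precede it.
#' @param baseline_s Baseline length in seconds (default 60).
#' @return Numeric z-scored vector.
#' @export
zscore_baseline <- function(time_s, trace, induction_s, baseline_s = 60) {
  stopifnot(length(time_s) == length(trace))
  base <- time_s >= induction_s - baseline_s & time_s < induction_s
  if (time_s[1L] > induction_s - baseline_s + 1e-9 || sum(base) < 2L) {
    stop(sprintf("window error: need %g s of pre-induction baseline", baseline_s),
         call. = FALSE)
  }
  m <- stats::median(trace[base])
  s <- stats::sd(trace[base])
  if (!is.finite(s) || s <= 0) {
    stop("degenerate-baseline error: baseline standard deviation is zero",
         call. = FALSE)
  }
  (trace - m) / s
}

#' Isosbestic motion correction
#'
#' Subtracts the z-scored 405 nm (isosbestic, calcium-independent) trace from
#' the z-scored 465 nm (calcium-dependent) trace, pointwise. Shared movement
#' artifacts appear in both channels and cancel; the 405 channel's own noise
#' propagates at unit z-weight, so cancellation is cleanest when artifacts
#' dominate (or match) both baselines.
#'
#' @param time_s Shared time grid in seconds.
#' @param z465 Z-scored 465 nm trace.
#' @param z405 Z-scored 405 nm trace on the same grid.
#' @param induction_s Seizure-induction time in seconds.
#' @param baseline_s Baseline length used for the z-scores (default 60 s).
#' @param analysis_window The detrend/analysis window `(start_s, end_s)`.
#' @return An object of class `corrected_trace`: `time_s`, `z`
#'   (`z465 - z405`), `induction_s`, `baseline_window`, `analysis_window`.
#' @export
motion_correct <- function(time_s, z465, z405, induction_s,
                           baseline_s = 60, analysis_window = NULL) {
  if (length(z465) != length(z405) || length(z465) != length(time_s)) {
    stop("alignment error: channel grids differ", call. = FALSE)
  }
  if (is.null(analysis_window)) {
    analysis_window <- c(time_s[1L], time_s[length(time_s)])
  }
  structure(list(time_s = time_s,
                 z = z465 - z405,
                 induction_s = induction_s,
                 baseline_window = c(induction_s - baseline_s, induction_s),
                 analysis_window = as.numeric(analysis_window)),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("<corrected_trace> %d samples, induction %g s, baseline [%g, %g) s\n",
              length(x$z), x$induction_s,
              x$baseline_window[1L], x$baseline_window[2L]))
  invisible(x)
}

#' @export
plot.corrected_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$z, type = "l", xlab = "Time (s)",
                 ylab = "Activity (z)", ...)
  graphics::abline(v = x$induction_s, lty = 2)
  invisible(x)
}

#' Full photometry correction pipeline
#'
#' Detrend (median-anchored line over the 6-min window centered on
#' induction), z-score each channel by its 60-s pre-induction baseline, then
#' subtract the isosbestic channel. If the record is shorter than the 6-min
#' window, the window clips to the record with a warning and the detrend
#' flanks shrink proportionally (minimum 10 s).
#'
#' @param prec A [photometry_recording].
#' @param analysis_half_width_s Half-width of the analysis window around
#'   induction (default 180 s, i.e. a 6-min window).
#' @param baseline_s Baseline length in seconds (default 60).
#' @param flank_s Detrend anchor flank length in seconds (default 50).
#' @return A `corrected_trace`.
#' @export
correct_photometry <- function(prec, analysis_half_width_s = 180,
                               baseline_s = 60, flank_s = 50) {
  stopifnot(inherits(prec, "photometry_recording"))
  t <- prec$time_s
  win <- c(prec$induction_s - analysis_half_width_s,
           prec$induction_s + analysis_half_width_s)
  rec_span <- c(t[1L], t[length(t)] + 1 / prec$fs)
  if (win[1L] < rec_span[1L] - 1e-9 || win[2L] > rec_span[2L] + 1e-9) {
    full <- diff(win)
    win <- c(max(win[1L], rec_span[1L]), min(win[2L], rec_span[2L]))
    flank_s <- max(10, flank_s * diff(win) / full)
    warning(sprintf(
      "analysis window clipped to [%g, %g) s; detrend flanks %.3g s",
      win[1L], win[2L], flank_s), call. = FALSE)
  }
  d465 <- detrend_linear(t, prec$f465, win, flank_s = flank_s)
  d405 <- detrend_linear(t, prec$f405, win, flank_s = flank_s)
  z465 <- zscore_baseline(t, d465, prec$induction_s, baseline_s = baseline_s)
  z405 <- zscore_baseline(t, d405, prec$induction_s, baseline_s = baseline_s)
  motion_correct(t, z465, z405, prec$induction_s,
                 baseline_s = baseline_s, analysis_window = win)
}

#' Pre- and during-seizure activity summaries
#'
#' The two predictors of the encoding model: mean corrected activity over the
#' 60 s before induction, and over the seizure interval
#' `[induction, induction + max(seizure_duration_s, stim_duration_s))`
#' (the stimulation window is the fallback when no after-discharge was
#' detected). Windows are half-open.
#'
#' @param ct A `corrected_trace`.
#' @param seizure_duration_s Ictal (after-discharge) duration in seconds;
#'   0 if no seizure was provoked.
#' @param stim_duration_s Stimulation-train duration in seconds (default 10).
#' @param baseline_s Pre-seizure window length in seconds (default 60).
#' @return An object of class `epoch_activity`: `pre_mean`, `during_mean`
#'   (z-units) and the two windows.
#' @export
epoch_activity <- function(ct, seizure_duration_s, stim_duration_s = 10,
                           baseline_s = 60) {
  stopifnot(inherits(ct, "corrected_trace"))
  check_scalar(seizure_duration_s, "seizure_duration_s", min = 0)
  ind <- ct$induction_s
  pre_win <- c(ind - baseline_s, ind)
  dur_win <- c(ind, ind + max(seizure_duration_s, stim_duration_s))
  pre <- ct$time_s >= pre_win[1L] & ct$time_s < pre_win[2L]
  dur <- ct$time_s >= dur_win[1L] & ct$time_s < dur_win[2L]
  if (sum(pre) < 2L || ct$time_s[1L] > pre_win[1L] + 1e-9) {
    stop("window error: insufficient pre-induction data", call. = FALSE)
  }
  if (sum(dur) < 1L) {
    stop("window error: no samples in the during-seizure window", call. = FALSE)
  }
  structure(list(pre_mean = mean(ct$z[pre]),
                 during_mean = mean(ct$z[dur]),
                 pre_window = pre_win,
                 during_window = dur_win),
            class = "epoch_activity")
}

#' @export
print.epoch_activity <- function(x, ...) {
  cat(sprintf("<epoch_activity> pre %.3f z, during %.3f z\n",
              x$pre_mean, x$during_mean))
  invisible(x)
}
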