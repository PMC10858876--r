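# Core data containers: EEG recordings, photometry recordings, hypnograms.

#' Construct an EEG recording
#'
#' A uniformly sampled voltage trace with stimulation-event annotations.
#' Time is in seconds from recording start; sample `i` is at `(i - 1) / fs`.
#'
#' @param samples Numeric vector of EEG samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param events Data frame of stimulation events with columns `onset_s`
#'   (seconds), `label` (character) and `stim_hz` (stimulation frequency, Hz).
#'   May have zero rows.
#' @return An object of class `eeg_recording` with elements `samples`, `fs`
#'   and `events`.
#' @examples
#' rec <- eeg_recording(rnorm(2000), fs = 1000)
#' rec
#' @export
eeg_recording <- function(samples, fs,
                          events = data.frame(onset_s = numeric(0),
                                              label = character(0),
                                              stim_hz = numeric(0))) {
  check_scalar(fs, "fs", min = 0, strict_min = TRUE)
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) stop("EEG samples must be finite", call. = FALSE)
  stopifnot(is.data.frame(events),
            all(c("onset_s", "label", "stim_hz") %in% names(events)))
  dur <- length(samples) / fs
  if (nrow(events) && any(events$onset_s < 0 | events$onset_s > dur)) {
    stop("event onsets must lie within [0, duration]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%.1f s), %d event(s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording` or `photometry_recording`.
#' @return Length of the record in seconds.
#' @export
rec_duration <- function(rec) length(rec$time_s %||% rec$samples) / rec$fs

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a dual-excitation photometry recording
#'
#' Paired 465 nm (calcium-dependent) and 405 nm (isosbestic) fluorescence
#' traces on a shared time base, already demultiplexed into one sample per
#' channel per tick.
#'
#' @param time_s Numeric time grid in seconds (strictly increasing, uniform).
#' @param f465 Raw 465 nm excitation fluorescence (arbitrary units).
#' @param f405 Raw 405 nm excitation fluorescence (arbitrary units).
#' @param induction_s Seizure-induction time in seconds; must lie inside the
#'   record.
#' @return An object of class `photometry_recording` with the effective
#'   per-channel sampling rate in `fs`.
#' @export
photometry_recording <- function(time_s, f465, f405, induction_s) {
  if (length(time_s) < 2L ||
      length(f465) != length(time_s) || length(f405) != length(time_s)) {
    stop("time_s, f465 and f405 must have equal length >= 2", call. = FALSE)
  }
  if (!all(is.finite(time_s)) || !all(is.finite(f465)) || !all(is.finite(f405))) {
    stop("photometry traces must be finite", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time_s must be a uniform, strictly increasing grid", call. = FALSE)
  }
  check_scalar(induction_s, "induction_s",
               min = time_s[1L], max = time_s[length(time_s)])
  structure(list(time_s = as.numeric(time_s), f465 = as.numeric(f465),
                 f405 = as.numeric(f405), fs = 1 / mean(dt),
                 induction_s = induction_s),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples/channel @ %.3g Hz, induction at %g s\n",
              length(x$time_s), x$fs, x$induction_s))
  invisible(x)
}

#' Construct a hypnogram
#'
#' An ordered sequence of fixed-length sleep-state epochs scored as
#' Wake / NREM / REM.
#'
#' @param states Character vector (or factor) of epoch labels, each one of
#'   `"Wake"`, `"NREM"`, `"REM"`.
#' @param epoch_s Epoch length in seconds (default 5).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_s = 5) {
  states <- as.character(states)
  if (length(states) < 1L) stop("hypnogram must be non-empty", call. = FALSE)
  bad <- setdiff(unique(states), c("Wake", "NREM", "REM"))
  if (length(bad)) {
    stop("unknown sleep state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_scalar(epoch_s, "epoch_s", min = 0, strict_min = TRUE)
  structure(list(states = states, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = c("Wake", "NREM", "REM")))
  cat(sprintf("<hypnogram> %d x %g-s epochs (%.1f min): Wake %d, NREM %d, REM %d\n",
              length(x$states), x$epoch_s,
              length(x$states) * x$epoch_s / 60, tab[1L], tab[2L], tab[3L]))
  invisible(x)
}

# ---- plain-text readers / writers -----------------------------------------

#' Read an EEG trace from a two-column CSV
#'
#' Expects columns `time_s` and `eeg_uV` on a uniform grid; events may be
#' supplied as a second CSV with columns `onset_s`, `label`, `stim_hz`.
#'
#' @param path Path to the EEG CSV.
#' @param events_path Optional path to the events CSV.
#' @return An [eeg_recording].
#' @export
read_eeg_csv <- function(path, events_path = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "eeg_uV") %in% names(d)))
  fs <- 1 / mean(diff(d$time_s))
  ev <- if (!is.null(events_path)) utils::read.csv(events_path) else
    data.frame(onset_s = numeric(0), label = character(0), stim_hz = numeric(0))
  eeg_recording(d$eeg_uV, fs = fs, events = ev)
}

#' Read a photometry recording from CSV
#'
#' Expects columns `time_s`, `f465`, `f405`.
#'
#' @param path Path to the photometry CSV.
#' @param induction_s Seizure-induction time in seconds.
#' @return A [photometry_recording].
#' @export
read_photometry_csv <- function(path, induction_s) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "f465", "f405") %in% names(d)))
  photometry_recording(d$time_s, d$f465, d$f405, induction_s = induction_s)
}

#' Read a hypnogram from CSV
#'
#' Expects columns `epoch_index` and `state`.
#'
#' @param path Path to the hypnogram CSV.
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A [hypnogram].
#' @export
read_hypnogram_csv <- function(path, epoch_s = 5) {
  d <- utils::read.csv(path)
  stopifnot("state" %in% names(d))
  if ("epoch_index" %in% names(d)) d <- d[order(d$epoch_index), , drop = FALSE]
  hypnogram(d$state, epoch_s = epoch_s)
}

#' Write a simulated session to plain-text files
#'
#' Writes `<prefix>_eeg.csv` (time_s, eeg_uV), `<prefix>_events.csv`
#' (onset_s, label, stim_hz) and `<prefix>_photometry.csv`
#' (time_s, f465, f405).
#'
#' @param session A `simulated_session` from [generate_session()].
#' @param prefix Output path prefix (directory must exist).
#' @return Invisibly, the written file paths.
#' @export
write_session_csv <- function(session, prefix) {
  stopifnot(inherits(session, "simulated_session"))
  eeg <- session$eeg
  t_eeg <- (seq_along(eeg$samples) - 1) / eeg$fs
  p <- c(eeg = paste0(prefix, "_eeg.csv"),
         events = paste0(prefix, "_events.csv"),
         phot = paste0(prefix, "_photometry.csv"))
  utils::write.csv(data.frame(time_s = t_eeg, eeg_uV = eeg$samples),
                   p[["eeg"]], row.names = FALSE)
  utils::write.csv(eeg$events, p[["events"]], row.names = FALSE)
  ph <- session$photometry
  utils::write.csv(data.frame(time_s = ph$time_s, f465 = ph$f465, f405 = ph$f405),
                   p[["phot"]], row.names = FALSE)
  invisible(p)
}

#' Write a hypnogram to CSV
#' @param h A [hypnogram].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hypnogram_csv <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(data.frame(epoch_index = seq_along(h$states) - 1L,
                              state = h$states),
                   path, row.names = FALSE)
  invisible(path)
}
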