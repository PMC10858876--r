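# EEG preprocessing and spectral quantification of seizure intensity.
#
# Conventions: Welch PSD over non-overlapping 1-s Hann-tapered segments,
# one-sided density in uV^2/Hz normalized so that the trapezoidal integral
# over [0, fs/2] equals the variance of the analyzed window (Parseval).
# "Band power" is that integral restricted to a band, in uV^2.

#' Filter an EEG recording (100 Hz low-pass, 50 Hz notch)
#'
#' Applies, zero-phase (forward-backward, so no phase distortion), a
#' fourth-order Butterworth low-pass at 100 Hz to suppress stimulation
#' artifacts, followed by a second-order notch centered at 50 Hz to remove
#' line noise. Length, sampling rate and event annotations are preserved.
#'
#' @param rec An [eeg_recording] with `fs > 200` Hz.
#' @param lowpass_hz Low-pass corner frequency in Hz (default 100).
#' @param notch_hz Notch center frequency in Hz (default 50).
#' @param notch_q Notch quality factor, center / -3 dB bandwidth (default 30,
#'   i.e. about 1.7 Hz wide at 50 Hz).
#' @return A filtered copy of `rec`.
#' @export
eeg_preprocess <- function(rec, lowpass_hz = 100, notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 200) {
    stop(sprintf("sampling-rate error: fs = %g Hz is too low (need > 200 Hz)",
                 rec$fs), call. = FALSE)
  }
  lp <- signal::butter(4, lowpass_hz / (rec$fs / 2), type = "low")
  x <- zp_filtfilt(lp, rec$samples)
  nf <- notch_biquad(notch_hz, rec$fs, notch_q)
  x <- zp_filtfilt(nf, x)
  out <- rec
  out$samples <- as.numeric(x)
  out
}

# One-pass IIR filter assuming the input sat at the constant x0 forever
# before x[1]: the FIR part sees a constant-extended input and the recursion
# starts from its DC steady state, so a constant trace passes exactly.
lfilter_steady <- function(b, a, x, x0) {
  b <- b / a[1L]
  a <- a / a[1L]
  nb <- length(b)
  xp <- c(rep(x0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[nb:length(xp)])
  if (length(a) > 1L) {
    y0 <- x0 * sum(b) / sum(a)
    y <- stats::filter(v, -a[-1L], method = "recursive",
                       init = rep(y0, length(a) - 1L))
  } else {
    y <- v
  }
  as.numeric(y)
}

# Zero-phase (forward-backward) filtering with odd-reflection edge padding,
# so edge transients decay inside the pad instead of contaminating the trace.
zp_filtfilt <- function(flt, x, padlen = NULL) {
  b <- flt$b / flt$a[1L]
  a <- flt$a / flt$a[1L]
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 1000L)
  if (padlen > 0L) {
    pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- lfilter_steady(b, a, ext, ext[1L])
  y <- rev(lfilter_steady(b, a, rev(y), y[length(y)]))
  y[seq(padlen + 1L, padlen + n)]
}

# Second-order (biquad) notch, standard constrained-pole-zero design:
# zeros on the unit circle at +/- w0, poles at radius set by the bandwidth
# w0 / Q. Returns an Arma filter usable with signal::filtfilt.
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1L], a = a / a[1L])
}

# Magnitude response |H(f)| of an Arma filter at frequencies f (Hz), as
# applied by filtfilt (squared magnitude of the single-pass response).
filter_gain <- function(flt, f, fs, zero_phase = TRUE) {
  z <- exp(-2i * pi * f / fs)
  h <- vapply(z, function(zz) {
    num <- sum(flt$b * zz^(seq_along(flt$b) - 1))
    den <- sum(flt$a * zz^(seq_along(flt$a) - 1))
    abs(num / den)
  }, numeric(1))
  if (zero_phase) h^2 else h
}

#' Welch power spectral density over 1-s epochs
#'
#' Segments the requested window into consecutive non-overlapping 1-s epochs,
#' applies a Hann taper to each, and averages the one-sided modified
#' periodograms. The density is scaled by `1 / (fs * sum(w^2))` (with the
#' usual factor 2 on interior frequencies) so that the integral of the PSD
#' over [0, fs/2] matches the variance of the analyzed signal.
#'
#' @param rec An [eeg_recording].
#' @param window Numeric length-2 vector `(start_s, end_s)`; half-open
#'   `[start, end)`, must lie within the recording and span at least 1 s.
#' @param detrend_segments Subtract each segment's mean before tapering
#'   (default TRUE); removes the DC leakage of slow offsets.
#' @return An object of class `spectral_estimate`: `frequencies` (Hz, spacing
#'   1 Hz from 0 to fs/2), `psd` (uV^2/Hz), `epoch_count`, `window`, `fs`,
#'   and `epoch_psd` (frequency x epoch matrix of per-epoch densities).
#' @export
welch_psd <- function(rec, window, detrend_segments = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2L)
  dur <- length(rec$samples) / rec$fs
  if (window[1L] < 0 || window[2L] > dur + 1e-9) {
    stop("window error: analysis window exceeds the recording", call. = FALSE)
  }
  if (diff(window) < 1 - 1e-9) {
    stop("window error: analysis window must span at least 1 s", call. = FALSE)
  }
  fs <- rec$fs
  nseg <- as.integer(fs)             # 1-s epochs
  idx <- window_idx(0, fs, length(rec$samples), window[1L], window[2L])
  n_ep <- length(idx) %/% nseg
  if (n_ep < 1L) stop("window error: no complete 1-s epoch in window", call. = FALSE)
  x <- rec$samples[idx[seq_len(n_ep * nseg)]]
  segs <- matrix(x, nrow = nseg, ncol = n_ep)
  w <- hann_window(nseg)
  if (detrend_segments) segs <- sweep(segs, 2L, colMeans(segs))
  segs <- segs * w
  spec <- Mod(stats::mvfft(segs))^2 / (fs * sum(w^2))
  nf <- nseg %/% 2L + 1L
  spec <- spec[seq_len(nf), , drop = FALSE]
  interior <- seq(2L, nf - 1L + (nseg %% 2L))  # double all but DC (and Nyquist)
  spec[interior, ] <- 2 * spec[interior, ]
  freqs <- (seq_len(nf) - 1L) * fs / nseg
  structure(list(frequencies = freqs,
                 psd = rowMeans(spec),
                 epoch_psd = spec,
                 epoch_count = n_ep,
                 window = as.numeric(window),
                 fs = fs),
            class = "spectral_estimate")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d epochs over [%g, %g) s, df = %g Hz\n",
              x$epoch_count, x$window[1L], x$window[2L],
              x$frequencies[2L] - x$frequencies[1L]))
  invisible(x)
}

#' Integrated band power of a spectral estimate
#'
#' Trapezoidal integral of the PSD over a frequency band; with the package's
#' PSD normalization the result is in uV^2 and Parseval-consistent.
#'
#' @param est A `spectral_estimate` from [welch_psd()].
#' @param band Length-2 numeric band in Hz (default `c(4, 14)`, the seizure
#'   band of interest).
#' @return An object of class `band_power_result`: `band_power` (uV^2),
#'   `band`, `window`.
#' @export
band_power <- function(est, band = c(4, 14)) {
  stopifnot(inherits(est, "spectral_estimate"), length(band) == 2L)
  if (band[1L] < est$frequencies[1L] - 1e-9 ||
      band[2L] > est$frequencies[length(est$frequencies)] + 1e-9 ||
      band[2L] <= band[1L]) {
    stop("argument error: band must lie within the frequency grid", call. = FALSE)
  }
  structure(list(band_power = band_integral(est$frequencies, est$psd, band),
                 band = as.numeric(band),
                 window = est$window),
            class = "band_power_result")
}

# trapezoidal integral of psd over [band1, band2], interpolating band edges
band_integral <- function(f, p, band) {
  lo <- max(band[1L], f[1L]); hi <- min(band[2L], f[length(f)])
  grid <- sort(unique(c(lo, f[f > lo & f < hi], hi)))
  pv <- stats::approx(f, p, xout = grid, rule = 2)$y
  sum(diff(grid) * (pv[-1L] + pv[-length(pv)]) / 2)
}

#' @export
print.band_power_result <- function(x, ...) {
  cat(sprintf("<band_power_result> %.4g uV^2 in %g-%g Hz over [%g, %g) s\n",
              x$band_power, x$band[1L], x$band[2L], x$window[1L], x$window[2L]))
  invisible(x)
}

#' Seizure band power for one induction
#'
#' The scalar measure of seizure intensity: the recording is filtered
#' ([eeg_preprocess()]), the Welch PSD is computed over the 30 s following
#' seizure induction, and the 4-14 Hz band power is integrated. This value is
#' the response variable of the encoding model.
#'
#' @param rec An [eeg_recording].
#' @param induction_s Seizure-induction (stimulation-onset) time in seconds.
#' @param analysis_s Length of the post-induction analysis window (default 30 s).
#' @param band Frequency band in Hz (default `c(4, 14)`).
#' @param preprocessed Set TRUE if `rec` is already filtered, to skip the
#'   filters.
#' @return A `band_power_result`.
#' @export
seizure_power <- function(rec, induction_s, analysis_s = 30, band = c(4, 14),
                          preprocessed = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  dur <- length(rec$samples) / rec$fs
  if (induction_s + analysis_s > dur + 1e-9) {
    stop("window error: post-induction analysis window exceeds the recording",
         call. = FALSE)
  }
  if (!preprocessed) rec <- eeg_preprocess(rec)
  est <- welch_psd(rec, c(induction_s, induction_s + analysis_s))
  band_power(est, band = band)
}

#' Time-frequency matrix of per-epoch power densities
#'
#' One Welch column per consecutive 1-s epoch; averaging the columns
#' reproduces [welch_psd()] of the same window.
#'
#' @inheritParams welch_psd
#' @return A list of class `eeg_spectrogram`: `frequencies` (Hz), `times`
#'   (epoch start times, s), `power` (frequency x epoch matrix, uV^2/Hz).
#' @export
eeg_spectrogram <- function(rec, window) {
  est <- welch_psd(rec, window)
  structure(list(frequencies = est$frequencies,
                 times = est$window[1L] + seq_len(est$epoch_count) - 1,
                 power = est$epoch_psd),
            class = "eeg_spectrogram")
}

#' @export
plot.eeg_spectrogram <- function(x, fmax = 30, ...) {
  keep <- x$frequencies <= fmax
  graphics::image(x$times, x$frequencies[keep],
                  t(log10(x$power[keep, , drop = FALSE] + 1e-12)),
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  main = "EEG power (log10 uV^2/Hz)", ...)
  invisible(x)
}
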