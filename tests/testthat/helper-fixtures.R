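# Shared fixtures, built in code at test time.

# pure sinusoid as an EEG recording
make_tone <- function(freq_hz, amp_uV, dur_s, fs = 1000, phase = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  eeg_recording(amp_uV * sin(2 * pi * freq_hz * t + phase), fs = fs)
}

# analytic magnitude response of the preprocessing chain (4th-order
# Butterworth low-pass + biquad notch), squared for the forward-backward
# application; evaluated directly from the transfer-function coefficients,
# independent of the filtering code path.
analytic_preprocess_gain <- function(f, fs = 1000,
                                     lowpass_hz = 100, notch_hz = 50,
                                     notch_q = 30) {
  lp <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * notch_q)
  nb <- c(1, -2 * cos(w0), 1)
  na <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  gain1 <- function(b, a, f) {
    z <- exp(-2i * pi * f / fs)
    vapply(z, function(zz) {
      abs(sum(b * zz^(seq_along(b) - 1)) / sum(a * zz^(seq_along(a) - 1)))
    }, numeric(1))
  }
  (gain1(lp$b, lp$a, f) * gain1(nb, na, f))^2
}

# config with all stochastic terms off except spontaneous calcium
# fluctuations (needed for a non-degenerate photometry baseline) and tiny
# per-channel measurement noise (needed for a non-degenerate 405 channel)
quiet_cfg <- function(...) {
  sim_config(noise_sd_eeg = 0, motion_sd = 0, bleach_slope = 0,
             amp_noise_sd = 0, photometry_noise_sd = 1e-3, ...)
}

# random hypnogram states (not via the package's Markov generator)
random_states <- function(n) {
  sample(c("Wake", "NREM", "REM"), n, replace = TRUE,
         prob = c(0.5, 0.35, 0.15))
}

# steady-state RMS of a trace, excluding edge fractions
mid_rms <- function(x, drop = 0.2) {
  n <- length(x)
  i <- seq.int(floor(n * drop) + 1L, ceiling(n * (1 - drop)))
  sqrt(mean(x[i]^2))
}
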