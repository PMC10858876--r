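# Synthetic peri-seizure sessions with known ground truth.
#
# Generative model (per session):
#   latent_pre    ~ TruncNormal(mean, sd, >= 0)   pre-seizure HON activity level
#   latent_during ~ TruncNormal(mean, sd, >= 0)   during-seizure HON surge level
#   EEG  = baseline noise
#        + stimulation artifact (sinusoid at stim_frequency for stim_duration)
#        + after-discharge: amplitude-modulated oscillation sweeping inside
#          the 4-14 Hz band for true_duration s after stimulation offset,
#          amplitude = ad_gain_uV * max(0, amp_base + beta_pre * latent_pre
#                        + beta_during * latent_during + amp_noise_sd * e)
#   F465 = offset * (1 - bleach_slope * t) + calcium + surge + motion + noise
#   F405 = offset * (1 - bleach_slope * t)                 + motion + noise
#
# The calcium component is a smooth AR(1) fluctuation plus a train of
# plateau-shaped transients in the late pre-induction baseline whose height
# is calibrated per session (root-finding on the realized samples) so that
# the corrected pre-seizure mean recovers pre_readout_gain * latent_pre.
# The baseline z-scoring bounds any pre-window mean by 1 in absolute value
# (|mean - median| <= SD for any sample), hence the linear gain < 1.

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic-session generator.
#' Defaults emulate the study conditions: 1 kHz EEG, 10 Hz-per-channel
#' demultiplexed photometry, 6-min sessions with induction at mid-session,
#' a 20 Hz / 10 s stimulation train, and a 4-14 Hz after-discharge.
#'
#' @param fs_eeg EEG sampling rate, Hz (default 1000).
#' @param fs_photometry Per-channel photometry rate, Hz (default 10).
#' @param session_length Session length, s (default 360, a 6-min window).
#' @param induction_time Seizure-induction time within the session, s
#'   (default 180).
#' @param stim_frequency Stimulation frequency, Hz; one of 5, 10, 20
#'   (default 20, the frequency that induces robust seizures).
#' @param stim_duration Stimulation-train length, s (default 10).
#' @param afterdischarge_band After-discharge frequency band, Hz
#'   (default `c(4, 14)`).
#' @param beta_pre Coupling of latent pre-seizure activity to after-discharge
#'   amplitude (unitless, default 1).
#' @param beta_during Coupling of during-seizure activity to after-discharge
#'   amplitude (default 0).
#' @param noise_sd_eeg Baseline EEG noise SD, uV (default 20).
#' @param eeg_noise Baseline noise color, `"white"` (default) or `"pink"`.
#' @param bleach_slope Linear photobleaching rate, fraction of the channel
#'   offset lost per second (default 8e-4, i.e. ~29% over 6 min).
#' @param motion_sd Shared motion-artifact SD, arbitrary fluorescence units
#'   (default 0.3).
#' @param calcium_sd SD of spontaneous calcium fluctuations, a.u. (default 1).
#' @param calcium_tau_s AR(1) correlation time of calcium fluctuations, s
#'   (default 1.5, a GCaMP6s-like timescale).
#' @param photometry_noise_sd Per-channel measurement noise SD, a.u.
#'   (default 0.02).
#' @param amp_base Baseline after-discharge amplitude term (unitless,
#'   default 1).
#' @param amp_noise_sd SD of the session-level after-discharge amplitude
#'   noise (unitless, default 0.25; sets the unexplained variance of seizure
#'   power and hence the encoding model's validation R-squared).
#' @param ad_gain_uV After-discharge amplitude per unitless amplitude unit,
#'   uV (default 40).
#' @param stim_amp_uV Stimulation-artifact amplitude, uV (default 200).
#' @param duration_mean_s,duration_sd_s,duration_range_s Truncated-normal
#'   parameters of the true ictal duration, s (defaults 25, 5, `c(5, 60)`).
#' @param latent_pre_mean,latent_pre_sd Truncated-normal (at 0) parameters of
#'   latent pre-seizure activity (defaults 1, 0.5).
#' @param latent_during_mean,latent_during_sd Truncated-normal parameters of
#'   the during-seizure surge level (defaults 3, 1).
#' @param pre_readout_gain Corrected-trace z-units per unit of latent
#'   pre-seizure activity (default 0.3; must keep the readout below the
#'   normalization bound of 1).
#' @param offset465,offset405 Channel offsets, a.u. (defaults 100, 80).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(fs_eeg = 1000, fs_photometry = 10,
                       session_length = 360, induction_time = 180,
                       stim_frequency = 20, stim_duration = 10,
                       afterdischarge_band = c(4, 14),
                       beta_pre = 1, beta_during = 0,
                       noise_sd_eeg = 20, eeg_noise = c("white", "pink"),
                       bleach_slope = 8e-4, motion_sd = 0.3,
                       calcium_sd = 1, calcium_tau_s = 1.5,
                       photometry_noise_sd = 0.02,
                       amp_base = 1, amp_noise_sd = 0.25, ad_gain_uV = 40,
                       stim_amp_uV = 200,
                       duration_mean_s = 25, duration_sd_s = 5,
                       duration_range_s = c(5, 60),
                       latent_pre_mean = 1, latent_pre_sd = 0.5,
                       latent_during_mean = 3, latent_during_sd = 1,
                       pre_readout_gain = 0.3,
                       offset465 = 100, offset405 = 80) {
  eeg_noise <- match.arg(eeg_noise)
  check_scalar(fs_eeg, "fs_eeg", min = 200, strict_min = TRUE)
  check_scalar(fs_photometry, "fs_photometry", min = 0, strict_min = TRUE)
  check_scalar(session_length, "session_length", min = 0, strict_min = TRUE)
  check_scalar(induction_time, "induction_time", min = 0, strict_min = TRUE)
  if (induction_time >= session_length) {
    stop("configuration error: `induction_time` must lie inside the session",
         call. = FALSE)
  }
  if (!stim_frequency %in% c(5, 10, 20)) {
    stop("configuration error: `stim_frequency` must be 5, 10 or 20 Hz",
         call. = FALSE)
  }
  check_scalar(stim_duration, "stim_duration", min = 0, strict_min = TRUE)
  stopifnot(length(afterdischarge_band) == 2L,
            afterdischarge_band[1L] > 0,
            afterdischarge_band[2L] > afterdischarge_band[1L],
            afterdischarge_band[2L] < fs_eeg / 2)
  for (nm in c("noise_sd_eeg", "motion_sd", "calcium_sd",
               "photometry_noise_sd", "amp_noise_sd",
               "latent_pre_sd", "latent_during_sd", "duration_sd_s")) {
    check_scalar(get(nm), nm, min = 0)
  }
  check_scalar(pre_readout_gain, "pre_readout_gain", min = 0, max = 0.8)
  cfg <- list(fs_eeg = fs_eeg, fs_photometry = fs_photometry,
              session_length = session_length, induction_time = induction_time,
              stim_frequency = stim_frequency, stim_duration = stim_duration,
              afterdischarge_band = as.numeric(afterdischarge_band),
              beta_pre = beta_pre, beta_during = beta_during,
              noise_sd_eeg = noise_sd_eeg, eeg_noise = eeg_noise,
              bleach_slope = bleach_slope, motion_sd = motion_sd,
              calcium_sd = calcium_sd, calcium_tau_s = calcium_tau_s,
              photometry_noise_sd = photometry_noise_sd,
              amp_base = amp_base, amp_noise_sd = amp_noise_sd,
              ad_gain_uV = ad_gain_uV, stim_amp_uV = stim_amp_uV,
              duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
              duration_range_s = as.numeric(duration_range_s),
              latent_pre_mean = latent_pre_mean, latent_pre_sd = latent_pre_sd,
              latent_during_mean = latent_during_mean,
              latent_during_sd = latent_during_sd,
              pre_readout_gain = pre_readout_gain,
              offset465 = offset465, offset405 = offset405)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %g-s session, induction %g s, %g Hz x %g s stim,\n",
           "  after-discharge %g-%g Hz, beta_pre %g, beta_during %g,",
           " EEG noise %g uV (%s)\n"),
    x$session_length, x$induction_time, x$stim_frequency, x$stim_duration,
    x$afterdischarge_band[1L], x$afterdischarge_band[2L],
    x$beta_pre, x$beta_during, x$noise_sd_eeg, x$eeg_noise))
  invisible(x)
}

rtruncnorm1 <- function(mean, sd, lo = 0, hi = Inf) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# unit-SD stationary AR(1) with correlation time tau (s)
ar1_noise <- function(n, fs, tau) {
  phi <- exp(-1 / (fs * tau))
  e <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# 1/f ("pink") noise with overall SD sd, via FFT amplitude shaping
pink_noise <- function(n, sd) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- 0:(n - 1L)
  f <- pmin(f, n - f)                     # conjugate-symmetric in FFT order
  f[1L] <- 1
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# Plateau-shaped transient train (values in [0, 1]) used to carry the latent
# pre-seizure activity: three bouts late in the 60-s baseline, covering ~45%
# of the window, with 0.5-s cosine ramps. Less than half the window stays
# elevated so the baseline median tracks the quiescent level.
pre_transient_template <- function(time_s, induction_s) {
  bouts <- rbind(c(-35, -26), c(-23, -13), c(-10, -2)) + induction_s
  b <- numeric(length(time_s))
  ramp <- 0.5
  for (k in seq_len(nrow(bouts))) {
    lo <- bouts[k, 1L]; hi <- bouts[k, 2L]
    inb <- time_s >= lo & time_s < hi
    tt <- time_s[inb]
    env <- rep(1, length(tt))
    env[tt < lo + ramp] <- 0.5 - 0.5 * cos(pi * (tt[tt < lo + ramp] - lo) / ramp)
    env[tt >= hi - ramp] <- 0.5 - 0.5 * cos(pi * (hi - tt[tt >= hi - ramp]) / ramp)
    b[inb] <- pmax(b[inb], env)
  }
  b
}

# (mean - median) / sd: what the baseline z-scored pre-window mean measures
asym_ratio <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(0)
  (mean(v) - stats::median(v)) / s
}

# Solve for the transient height h so that the realized baseline samples
# fluct + h * template have asymmetry ratio = target.
calibrate_transient_height <- function(fluct, template, target) {
  if (stats::sd(template) == 0) return(0)
  f <- function(h) asym_ratio(fluct + h * template) - target
  lo <- -200; hi <- 200
  if (f(lo) * f(hi) > 0) return(if (target >= 0) hi else lo)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

# cosine-ramped rectangular envelope over [on, off) with ramp length ramp_s
smooth_gate <- function(time_s, on, off, ramp_s = 0.5) {
  g <- numeric(length(time_s))
  inw <- time_s >= on & time_s < off
  tt <- time_s[inw]
  ramp_s <- min(ramp_s, (off - on) / 2)
  env <- rep(1, length(tt))
  if (ramp_s > 0) {
    env[tt < on + ramp_s] <- 0.5 - 0.5 * cos(pi * (tt[tt < on + ramp_s] - on) / ramp_s)
    env[tt >= off - ramp_s] <- 0.5 - 0.5 * cos(pi * (off - tt[tt >= off - ramp_s]) / ramp_s)
  }
  g[inw] <- env
  g
}

#' Generate one synthetic peri-seizure session
#'
#' Produces a coupled EEG + photometry session with known ground truth:
#' a stimulation artifact, an after-discharge whose amplitude is driven by
#' the latent pre- (and optionally during-) seizure activity, and a
#' dual-channel photometry trace carrying bleaching, shared motion, calcium
#' fluctuations, pre-seizure transients and a during-seizure surge.
#' Deterministic given `(cfg, seed)`; the caller's RNG stream is untouched.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param latent_pre,latent_during Optional fixed latent activity levels
#'   (z-like units, >= 0); drawn from the configured truncated normals when
#'   NULL.
#' @return An object of class `simulated_session`: `eeg` ([eeg_recording]),
#'   `photometry` ([photometry_recording]) and `truth` (list with
#'   `latent_pre`, `latent_during`, `true_afterdischarge_power` (uV^2, over
#'   the 30-s post-induction window), `true_duration` (s), `amplitude_uV`,
#'   `motion_trace`).
#' @examples
#' s <- generate_session(sim_config(), seed = 1)
#' s$truth$latent_pre
#' @export
generate_session <- function(cfg, seed, latent_pre = NULL, latent_during = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    if (is.null(latent_pre)) {
      latent_pre <- rtruncnorm1(cfg$latent_pre_mean, cfg$latent_pre_sd, lo = 0)
    }
    if (is.null(latent_during)) {
      latent_during <- rtruncnorm1(cfg$latent_during_mean, cfg$latent_during_sd,
                                   lo = 0)
    }
    check_scalar(latent_pre, "latent_pre", min = 0)
    check_scalar(latent_during, "latent_during", min = 0)
    ind <- cfg$induction_time
    offset_s <- ind + cfg$stim_duration

    ## ---- true after-discharge parameters --------------------------------
    true_duration <- rtruncnorm1(cfg$duration_mean_s, cfg$duration_sd_s,
                                 lo = cfg$duration_range_s[1L],
                                 hi = min(cfg$duration_range_s[2L],
                                          cfg$session_length - offset_s - 1))
    amp_units <- cfg$amp_base + cfg$beta_pre * latent_pre +
      cfg$beta_during * latent_during +
      cfg$amp_noise_sd * stats::rnorm(1L)
    amplitude_uV <- cfg$ad_gain_uV * max(0, amp_units)

    ## ---- EEG -------------------------------------------------------------
    n <- round(cfg$session_length * cfg$fs_eeg)
    t <- (seq_len(n) - 1) / cfg$fs_eeg
    eeg <- if (cfg$noise_sd_eeg > 0) {
      if (cfg$eeg_noise == "white") stats::rnorm(n, sd = cfg$noise_sd_eeg)
      else pink_noise(n, cfg$noise_sd_eeg)
    } else numeric(n)
    stim_gate <- t >= ind & t < offset_s
    eeg[stim_gate] <- eeg[stim_gate] +
      cfg$stim_amp_uV * sin(2 * pi * cfg$stim_frequency * t[stim_gate])
    # after-discharge: frequency sweep inside the band, cosine-ramped envelope
    band <- cfg$afterdischarge_band
    f_mid <- mean(band); f_dev <- diff(band) * 0.25
    inst_f <- f_mid + f_dev * sin(2 * pi * 0.07 * (t - offset_s))
    phase <- 2 * pi * cumsum(inst_f) / cfg$fs_eeg
    env <- smooth_gate(t, offset_s, offset_s + true_duration, ramp_s = 0.5)
    ad <- amplitude_uV * env * sin(phase)
    eeg <- eeg + ad
    in30 <- t >= ind & t < ind + 30
    true_power <- sum(ad[in30]^2) / sum(in30)   # Parseval: band power in uV^2
    events <- data.frame(onset_s = ind, label = "stim",
                         stim_hz = cfg$stim_frequency)
    eeg_rec <- eeg_recording(eeg, fs = cfg$fs_eeg, events = events)

    ## ---- photometry ------------------------------------------------------
    np <- round(cfg$session_length * cfg$fs_photometry)
    tp <- (seq_len(np) - 1) / cfg$fs_photometry
    fluct <- if (cfg$calcium_sd > 0) {
      cfg$calcium_sd * ar1_noise(np, cfg$fs_photometry, cfg$calcium_tau_s)
    } else numeric(np)
    template <- pre_transient_template(tp, ind)
    base_idx <- tp >= ind - 60 & tp < ind
    motion <- if (cfg$motion_sd > 0) {
      cfg$motion_sd * ar1_noise(np, cfg$fs_photometry, 0.3)
    } else numeric(np)
    eps <- function() {
      if (cfg$photometry_noise_sd > 0)
        stats::rnorm(np, sd = cfg$photometry_noise_sd) else numeric(np)
    }
    eps465 <- eps(); eps405 <- eps()
    # Calibrate the transient height on the realized composite so that the
    # correction pipeline (z465 - z405) reads out gain * latent_pre in the
    # pre-window: the 405 channel's own baseline asymmetry is compensated.
    target <- max(-0.8, min(0.8, cfg$pre_readout_gain * latent_pre)) +
      asym_ratio(motion[base_idx] + eps405[base_idx])
    comp_base <- (fluct + motion + eps465)[base_idx]
    h <- if (cfg$calcium_sd > 0) {
      calibrate_transient_height(comp_base, template[base_idx], target)
    } else 0
    calcium <- fluct + h * template
    sd_b <- stats::sd(calcium[base_idx] + motion[base_idx] + eps465[base_idx])
    surge_gate <- smooth_gate(tp, ind, offset_s + true_duration, ramp_s = 1)
    surge <- latent_during * max(sd_b, 1e-12) * surge_gate
    bleach465 <- cfg$offset465 * (1 - cfg$bleach_slope * tp)
    bleach405 <- cfg$offset405 * (1 - cfg$bleach_slope * tp)
    f465 <- bleach465 + calcium + surge + motion + eps465
    f405 <- bleach405 + motion + eps405
    prec <- photometry_recording(tp, f465, f405, induction_s = ind)

    structure(list(
      eeg = eeg_rec,
      photometry = prec,
      truth = list(latent_pre = latent_pre,
                   latent_during = latent_during,
                   true_afterdischarge_power = true_power,
                   true_duration = true_duration,
                   amplitude_uV = amplitude_uV,
                   motion_trace = motion),
      config = cfg,
      seed = as.integer(seed)),
      class = "simulated_session")
  })
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf(
    "<simulated_session> seed %d: latent_pre %.2f, latent_during %.2f, duration %.1f s, AD amp %.1f uV\n",
    x$seed, x$truth$latent_pre, x$truth$latent_during,
    x$truth$true_duration, x$truth$amplitude_uV))
  invisible(x)
}

#' Generate a cohort of independent synthetic sessions
#'
#' Per-session seeds are derived deterministically from the master seed, so
#' a cohort is reproducible as a whole while its sessions are mutually
#' independent; session `i` of a cohort equals
#' `generate_session(cfg, derive_session_seed(seed, i))`.
#'
#' @param cfg A [sim_config()].
#' @param n_sessions Number of sessions (>= 1; the study analyzed 30
#'   recordings).
#' @param seed Master integer seed.
#' @return List of `simulated_session` objects.
#' @export
generate_cohort <- function(cfg, n_sessions, seed) {
  if (!is.numeric(n_sessions) || length(n_sessions) != 1L || n_sessions < 1) {
    stop("argument error: `n_sessions` must be >= 1", call. = FALSE)
  }
  lapply(seq_len(n_sessions), function(i) {
    generate_session(cfg, derive_session_seed(seed, i))
  })
}

#' Derive the seed of session `index` within a cohort
#' @param master_seed Cohort master seed.
#' @param index Session index (1-based).
#' @return Integer seed below 2^31.
#' @export
derive_session_seed <- function(master_seed, index) derive_seed(master_seed, index)

#' Generate a Markov-chain hypnogram
#'
#' Simulates a sequence of 5-s sleep-state epochs (Wake / NREM / REM) from a
#' first-order Markov chain.
#'
#' @param transition_matrix 3x3 row-stochastic matrix; rows/columns ordered
#'   Wake, NREM, REM (rows must sum to 1 within 1e-9, entries >= 0).
#' @param n_epochs Number of epochs (>= 1).
#' @param seed Integer seed.
#' @param init_state Initial state label (default `"Wake"`).
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A [hypnogram].
#' @export
generate_hypnogram <- function(transition_matrix, n_epochs, seed,
                               init_state = "Wake", epoch_s = 5) {
  P <- as.matrix(transition_matrix)
  if (!is.numeric(P) || any(dim(P) != c(3L, 3L)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("argument error: `transition_matrix` must be 3x3 row-stochastic",
         call. = FALSE)
  }
  if (!is.numeric(n_epochs) || length(n_epochs) != 1L || n_epochs < 1) {
    stop("argument error: `n_epochs` must be >= 1", call. = FALSE)
  }
  states <- c("Wake", "NREM", "REM")
  s0 <- match(match.arg(init_state, states), states)
  with_seed(seed, {
    out <- integer(n_epochs)
    out[1L] <- s0
    if (n_epochs > 1L) {
      u <- stats::runif(n_epochs - 1L)
      cum <- t(apply(P, 1L, cumsum))
      for (i in 2L:n_epochs) {
        out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ]) + 1L
      }
    }
    hypnogram(states[out], epoch_s = epoch_s)
  })
}
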