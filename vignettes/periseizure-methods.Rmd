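---
title: "Peri-seizure analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-seizure analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science and the engineering decisions behind
`periseizure`: what each stage computes, why the defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The measurement problem

An optogenetic stimulation train (20 Hz, 10 s) delivered to hippocampal CA1
provokes an electrographic seizure whose signature is a rhythmic 4–14 Hz
after-discharge on the EEG. Fiber photometry of hypocretin/orexin neurons
(HONs) runs simultaneously on two excitation wavelengths: 465 nm reports
calcium-dependent fluorescence, 405 nm is an isosbestic control that reports
movement artifacts but not calcium. The analysis asks how HON activity in
two epochs — the 60 s before induction and the seizure interval itself —
relates to seizure intensity.

## EEG quantification

**Filtering.** The raw trace is low-passed at 100 Hz (fourth-order
Butterworth) and notched at 50 Hz (second-order constrained-pole-zero
biquad, quality factor 30, i.e. a ~1.7 Hz wide notch). Both filters are
applied forward-backward, so the pass is zero-phase and the effective
magnitude response is the squared single-pass response. The implementation
pads each trace by odd reflection (up to 1000 samples per side) and starts
each pass from its DC steady state, so a constant trace passes bit-exactly
and edge transients decay inside the pad rather than contaminating the
recording.

**Welch PSD.** The analysis window is segmented into consecutive,
non-overlapping 1-s epochs; each epoch is mean-subtracted, Hann-tapered and
periodogram-transformed; the one-sided densities are averaged. The
normalization is `|FFT(w·x)|² / (fs · Σw²)` with the usual factor two on
interior frequencies, chosen so that the trapezoidal integral of the PSD
over [0, fs/2] equals the variance of the analyzed signal (Parseval). With
1-s epochs the frequency resolution is 1 Hz.

**Band power.** "Seizure power" is the integral of the PSD over 4–14 Hz, in
µV², over the 30 s after induction. An alternative reading — the per-bin
mean over the band — differs only by the constant bandwidth factor; the
integral was chosen because its units support exact Parseval checks (a
sinusoid of amplitude A contributes A²/2). Windows are half-open
`[start, end)` in seconds from recording start, everywhere in the package.

## Photometry correction

Each channel is detrended by subtracting the straight line through
(median time, median value) of the first and last 50 s of the 6-min window
centered on induction. Median anchors make the line insensitive to
transients, unlike a least-squares fit; anchoring the abscissa at the median
*sample time* makes an exactly linear trace detrend to zero on any grid. If
a record is shorter than 6 min the window clips with a warning and the
flanks shrink proportionally (minimum 10 s).

Each detrended channel is z-scored by the median and ordinary standard
deviation (the published pairing; not the MAD) of its 60-s pre-induction
baseline, and the corrected trace is the pointwise difference
`z465 − z405`. Two consequences of this normalization are worth stating
plainly:

- **Gain and offset invariance is exact; drift invariance is approximate.**
  Rescaling a raw channel by any positive constant, or adding a shared
  constant offset, leaves the corrected trace bit-identical (z-scores absorb
  gain; medians shift additively under constants). A shared *linear drift*
  cancels only up to the non-additivity of flank medians: in simulation the
  residual is a few hundredths of a z-unit, which is the tolerance the tests
  assert.
- **The pre-seizure mean is bounded.** The pre-seizure summary is the mean
  of the corrected trace over the same 60-s window that supplies the z-score
  baseline, i.e. `(mean − median)/SD` of that window — and for any sample
  `|mean − median| ≤ SD`. The pre-seizure readout therefore lives in
  [−1, 1] by construction and measures the *asymmetry* (transient load) of
  baseline activity, not its absolute level. This is a property of the
  published normalization, not of this implementation.
- **Isosbestic subtraction in z-units assumes comparable artifact scale.**
  Because each channel is self-normalized before subtraction, motion cancels
  cleanly when it dominates (or matches) both baselines; when the 405
  channel is nearly flat its z-score amplifies noise at unit weight. The
  subtraction is implemented exactly as published — no per-channel scaling
  or regression step is inserted, since none is described.

Degenerate inputs fail loudly: a zero baseline SD raises a
degenerate-baseline error, and the pipeline quarantines such sessions with a
logged reason rather than aborting the cohort.

The during-seizure window is `[induction, induction + max(duration, 10 s))`,
using the detected ictal duration and falling back to the 10-s stimulation
window when no after-discharge was detected.

## Encoding model

The model is a Gaussian identity-link GLM (ordinary least squares with
intercept): seizure band power as response, pre- and during-seizure mean
activity as predictors. Per bootstrap iteration: (1) rows are split 70/30
into training and validation; (2) training rows are resampled with
replacement; (3) the full model and each drop-one model are fit on the
resample; (4) each model is scored by R² on the untouched validation rows,
with SST about the validation set's own mean. After `n_boot` iterations the
contribution of predictor *j* is `max(0, mean R²_full − mean R²_−j)`;
relative contributions normalize the clipped declines to sum to one (all
zero when nothing helps). Raw declines are retained in the returned object.

Open points decided here:

- **Fresh split per iteration.** Whether the 70/30 split is drawn once or
  per iteration is ambiguous; re-splitting each iteration averages over
  split variance and matches the spirit of random bootstrapping, so it is
  the default (`resplit = FALSE` fixes a single split).
- **Validation rows are never resampled** — the bootstrap applies to
  training rows only.
- **Negative validation R² is kept.** Clipping applies to contributions
  only; `r_squared_full` may be negative. With very small cohorts the
  validation set can have as few as 2–4 rows and per-iteration R² is then
  heavy-tailed (occasionally enormously negative when the validation SST is
  tiny); the statistic is well-behaved at the intended scale of ~30
  recordings (9 validation rows). This is a property of the procedure, not
  a numerical artifact.
- **Family choice.** The response is a continuous, positive power; the
  Gaussian identity link is the natural reading of a "glmfit" on such data.

## After-discharge detection

The published seizure call was visual; the package substitutes an explicit
threshold rule and labels it as such in reports. The 4–14 Hz band power is
computed in consecutive 1-s epochs; the threshold is the pre-induction
baseline mean plus `k_sd = 3` baseline SDs over 60 s; supra-threshold runs
after stimulation offset are merged across gaps of ≤ 2 s; the seizure is
provoked iff a merged run starting within 5 s of stimulation offset lasts
≥ 2 s, and that run's whole span is the ictal duration. All four constants
are exposed as arguments and echoed into pipeline reports.

## Sleep and behavior metrics

A behavioral bout is a maximal run of identical 5-s epochs; the
fragmentation index of a state is bouts/epochs, in (0, 1]: 1/n for a single
consolidated bout, 1 for maximal fragmentation. State percentages are epoch
counts over a caller-supplied phase mask (light/dark bookkeeping is the
caller's). Seizure probability is the exact count ratio with half-up
integer rounding for display. Sucrose preference is consumed
sucrose / total consumed.

## The synthetic-data generator

The generator exists so that every stage has a ground truth. Per session,
a latent pre-seizure activity level `L_pre ~ TruncNormal(1, 0.5, ≥0)` and a
during-seizure surge level `L_during ~ TruncNormal(3, 1, ≥0)` drive:

- **EEG**: white Gaussian baseline noise (20 µV SD; a 1/f option exists but
  white noise keeps analytic band-power checks exact), a 200 µV stimulation
  artifact at the stimulation frequency, and an after-discharge whose
  instantaneous frequency sweeps inside 4–14 Hz for a truncated-normal
  duration (mean 25 s, SD 5 s) with amplitude
  `40 µV · max(0, 1 + β_pre·L_pre + β_during·L_during + 0.25·ε)`.
  The coupling is linear in amplitude, hence quadratic in power — the
  simplest monotone choice, and one that parameter-recovery tests can
  predict exactly.
- **Photometry**: both channels carry a linear bleach (0.08%/s of the
  offset), shared AR(1) motion, and independent measurement noise; the 465
  channel adds AR(1) calcium fluctuations (1.5-s correlation time, a
  GCaMP6s-like scale), a train of plateau-shaped pre-induction transients,
  and a during-seizure surge scaled to read out `L_during` in baseline
  z-units.

Because the pre-seizure readout is bounded by 1 (see above), the generator
cannot make the corrected pre-window mean equal `L_pre` itself for the
default latent distribution. Instead it couples `L_pre` to the *asymmetry*
of the baseline transients through a fixed linear gain
(`pre_readout_gain = 0.3` z-units per latent unit), calibrating the
transient height per session by root-finding on the realized samples (the
generator accounts for its own noise realizations, including the 405
channel's baseline asymmetry). The readout is therefore
`pre_mean ≈ 0.3·L_pre`, saturating only beyond `L_pre ≈ 2.7` (negligible
mass). Every correlation- and contribution-level property is invariant to
this positive rescaling of the predictor, and recovery tests assert
`pre_mean / 0.3` against `L_pre`.

**Noise calibration.** The single free noise knob that sets the encoding
model's achievable validation R² is the after-discharge amplitude noise
`amp_noise_sd`. It was calibrated once by simulating default cohorts
(n = 30) over a grid of candidate values and fixed at 0.25, which places the
mean validation R² near 0.5 at the study scale; it is an ordinary config
field and is not adjusted elsewhere.

**Markov hypnograms** draw 5-s epochs from a user-supplied 3×3
row-stochastic transition matrix; determinism and convergence to the
stationary distribution are tested against the eigenvector oracle.

**Seeding.** Every generator is a pure function of (config, seed): it runs
on a local RNG stream and restores the caller's. Cohort session seeds are
derived from the master seed by a fixed integer mix
(`derive_session_seed`), so cohorts are reproducible while sessions are
independent.

What the generator does **not** emulate: realistic EEG spectra (no 1/f
background by default, no spindles/theta structure), EMG, interleaved-
excitation demodulation (channels are generated already demultiplexed, as
the recording system delivers them), hemodynamic or wavelength-dependent
bleaching differences, behavioral video, or any biophysics of HON networks.
Passing tests on this generator therefore demonstrate correctness of the
*analysis operations* and recoverability of the generative couplings — not
that the pipeline is robust to every artifact class in real recordings.

## Problem sizes in the tests

The validation suite runs the full chain on 20 independent 30-session
cohorts (the study's cohort size) with 1000 bootstrap iterations — a size
chosen to keep the whole suite in the minutes range while leaving the
binomial margins of the ≥95%-of-seeds criteria intact; the published
statistic used 5000 iterations, and `n_boot = 5000` remains the function
default. Null cohorts (β_pre = 0) check that no contribution is invented.
Spectral oracles use 30-s tones; hypnogram oracles use 1000 random
sequences against a run-length-encoding reference.

## Known limitations

- The after-discharge detector is a surrogate for visual scoring; its
  thresholds are honest defaults, not fitted to any human-scored data.
- The isosbestic subtraction inherits the published method's z-unit
  convention, with the artifact-scale caveat above.
- The pre-seizure activity readout is bounded by the normalization; between
  sessions it is a monotone (linear, then saturating) transform of the
  latent level, which leaves correlations and contributions meaningful but
  means absolute z-values should not be compared across normalization
  schemes.
- EDF input is not supported; EEG is read from two-column CSV.
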