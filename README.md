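# periseizure

Quantitative analysis of acutely induced seizures recorded with simultaneous
EEG and hypothalamic fiber photometry in mice.

In the acute-epilepsy paradigm this package targets, brief optogenetic
stimulation of hippocampal CA1 (20 Hz for 10 s) provokes an
electrographic seizure: a rhythmic 4–14 Hz *after-discharge* that outlasts
the stimulation train. Simultaneously, the population calcium activity of
hypocretin/orexin neurons (HONs) in the lateral hypothalamus is recorded by
dual-excitation fiber photometry (465 nm calcium-dependent, 405 nm
isosbestic). The scientific question is which phase of HON activity —
the minute *before* seizure induction, or the surge *during* the seizure —
accounts for the intensity of the seizure.

The package implements the full analysis chain plus a synthetic-data
generator with known ground truth, so every stage is testable without the
original recordings:

- **EEG spectral quantification** — zero-phase 100 Hz low-pass and
  second-order 50 Hz notch; Welch PSD over non-overlapping 1-s Hann-tapered
  epochs; seizure intensity as the integrated 4–14 Hz band power over the
  30 s after induction, `P = ∫₄¹⁴ S(f) df` (µV², Parseval-consistent).
- **Photometry correction** — median-anchored linear bleach detrend over
  the 6-min window centered on induction; per-channel z-scoring by the
  median and SD of the 60-s pre-induction baseline; motion correction by
  isosbestic subtraction, `z = z₄₆₅ − z₄₀₅`; pre- and during-seizure mean
  activity.
- **Encoding model** — a Gaussian identity-link GLM predicting seizure
  power from (pre, during) activity. Per bootstrap iteration: 70/30
  train/validation split, training rows resampled with replacement, full and
  drop-one fits, validation R². The *contribution* of predictor *j* is
  `max(0, mean R²_full − mean R²_−j)`; relative contributions are the
  normalized shares.
- **Physiology metrics** — threshold-based after-discharge detection and
  ictal duration, seizure probability (provoked / total stimulations),
  sleep fragmentation index (bouts / epochs per state), state-time
  percentages, sucrose preference index.
- **Synthetic data** — seeded generator of coupled EEG + photometry
  sessions in which a latent pre-seizure activity level drives the
  after-discharge amplitude, plus Markov-chain hypnograms.

## Worked example

```r
library(periseizure)

# one synthetic session with known ground truth
s <- generate_session(sim_config(), seed = 7)
s
#> <simulated_session> seed 7: latent_pre 2.14, latent_during 1.80, duration 21.5 s, AD amp 121.6 uV

seizure_power(s$eeg, induction_s = 180)
#> <band_power_result> 4886 uV^2 in 4-14 Hz over [180, 210) s

# full pipeline on a cohort of 30 recordings
rep <- run_experiment(list(seed = 7, n_sessions = 30,
                           analysis = list(n_boot = 1000)))
rep
#> <run_report> 30 sessions analyzed (0 excluded), seed 7
#>   seizure probability: 100.0%
#>   r(pre, power)    = +0.853 (p = 2.19e-09)
#>   r(during, power) = -0.293 (p = 0.117)
#> <contribution_result> n = 30, 1000 bootstrap iterations (train fraction 0.70)
#>   validation R^2 (full model): 0.448
#>   pre_mean     decline 0.9164  relative 1.000
#>   during_mean  decline 0.0000  relative 0.000
```

Reading the output: each of the 30 stimulations provoked a detected
after-discharge; seizure band power correlates strongly and positively with
the corrected pre-seizure HON activity but not with during-seizure activity;
and the bootstrap drop-one analysis attributes essentially all of the
encoding model's held-out predictive performance (validation R² ≈ 0.45) to
the pre-seizure predictor — the generator's ground truth, since these
sessions were simulated with the after-discharge amplitude coupled to the
latent pre-seizure level only.

A thin command-line wrapper is installed at `inst/exec/periseizure`
(subcommands `simulate`, `run`, `contrib`, `sleep`).

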