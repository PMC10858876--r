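Package: periseizure
Title: Peri-Seizure EEG and Fiber-Photometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of acutely induced seizures recorded with
    simultaneous EEG and hypothalamic fiber photometry in mice. Provides EEG
    preprocessing (100 Hz low-pass, 50 Hz notch), Welch power spectral density
    on 1-s epochs and 4-14 Hz seizure band power; dual-excitation (465/405 nm)
    photometry correction (median-anchored linear bleach detrend, baseline
    z-scoring, isosbestic subtraction) with pre- and during-seizure activity
    summaries; a bootstrap drop-one generalized linear encoding model that
    scores the relative contribution of each activity epoch to seizure power;
    after-discharge detection, seizure probability, sleep fragmentation and
    sucrose preference metrics; and a seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
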