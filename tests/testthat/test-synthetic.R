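test_that("session generation is a pure function of (config, seed)", {
  cfg <- sim_config()
  a <- generate_session(cfg, seed = 3)
  b <- generate_session(cfg, seed = 3)
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$photometry$f465, b$photometry$f465)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$eeg$samples,
                         generate_session(cfg, seed = 4)$eeg$samples))
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_session(cfg, seed = 3)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("config invariants are enforced with named fields", {
  expect_error(sim_config(induction_time = 400), "induction_time")
  expect_error(sim_config(stim_frequency = 7), "stim_frequency")
  expect_error(sim_config(noise_sd_eeg = -1), "noise_sd_eeg")
  expect_error(sim_config(stim_duration = 0), "stim_duration")
  expect_error(sim_config(fs_eeg = 150), "fs_eeg")
})

test_that("with all noise sources off the photometry channels are constant", {
  cfg <- sim_config(calcium_sd = 0, motion_sd = 0, bleach_slope = 0,
                    photometry_noise_sd = 0, noise_sd_eeg = 0)
  s <- generate_session(cfg, seed = 1)
  expect_lt(diff(range(s$photometry$f405)), 1e-9)
  expect_lt(diff(range(s$photometry$f465)), 1e-6)
})

test_that("seizure band power grows with latent pre-seizure activity", {
  cfg <- quiet_cfg(beta_pre = 1, beta_during = 0)
  p1 <- seizure_power(generate_session(cfg, 7, latent_pre = 1)$eeg, 180)$band_power
  p2 <- seizure_power(generate_session(cfg, 7, latent_pre = 2)$eeg, 180)$band_power
  expect_gt(p2, p1)
})

test_that("true after-discharge power matches the measured band power", {
  cfg <- quiet_cfg()
  for (sd_ in 11:13) {
    s <- generate_session(cfg, sd_)
    meas <- seizure_power(s$eeg, 180)$band_power
    expect_equal(meas, s$truth$true_afterdischarge_power, tolerance = 0.02)
  }
})

test_that("cohorts derive distinct, reproducible per-session seeds", {
  cfg <- sim_config()
  coh <- generate_cohort(cfg, 30, seed = 5)
  lp <- vapply(coh, function(s) s$truth$latent_pre, numeric(1))
  expect_length(unique(lp), 30)
  one <- generate_cohort(cfg, 1, seed = 5)[[1L]]
  direct <- generate_session(cfg, derive_session_seed(5, 1))
  expect_identical(one$eeg$samples, direct$eeg$samples)
  lp2 <- vapply(generate_cohort(cfg, 5, seed = 6),
                function(s) s$truth$latent_pre, numeric(1))
  expect_false(identical(lp[1:5], lp2))
  expect_error(generate_cohort(cfg, 0, seed = 1), "n_sessions")
})

test_that("Markov hypnograms honor the transition matrix", {
  expect_error(generate_hypnogram(matrix(1, 3, 3), 10, 1), "stochastic")
  # absorbing identity chain stays in its initial state
  h <- generate_hypnogram(diag(3), 50, seed = 2, init_state = "Wake")
  expect_true(all(h$states == "Wake"))
  expect_identical(generate_hypnogram(diag(3), 20, 3)$states,
                   generate_hypnogram(diag(3), 20, 3)$states)
  # ergodic chain: empirical fractions approach the stationary distribution
  P <- rbind(c(0.90, 0.08, 0.02),
             c(0.10, 0.85, 0.05),
             c(0.20, 0.10, 0.70))
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.max(Re(ev$values))])
  stat <- stat / sum(stat)
  h2 <- generate_hypnogram(P, 1e5, seed = 4)
  emp <- as.numeric(table(factor(h2$states,
                                 c("Wake", "NREM", "REM")))) / 1e5
  expect_lt(max(abs(emp - stat)), 0.01)
})

test_that("noise-free sessions are recovered by the analysis pipeline", {
  cfg <- quiet_cfg()
  for (sd_ in c(21, 22, 23)) {
    s <- generate_session(cfg, sd_)
    out <- detect_afterdischarge(s$eeg, 180)
    expect_true(out$provoked)
    expect_lt(abs(out$duration_s - s$truth$true_duration), 1)
    ea <- epoch_activity(correct_photometry(s$photometry),
                         seizure_duration_s = out$duration_s)
    expect_equal(ea$pre_mean / cfg$pre_readout_gain, s$truth$latent_pre,
                 tolerance = 0.05)
  }
})

test_that("session CSV round-trips through the readers", {
  cfg <- sim_config(session_length = 130, induction_time = 100,
                    duration_mean_s = 12, duration_range_s = c(5, 18))
  s <- generate_session(cfg, 6)
  dir <- withr::local_tempdir()
  paths <- write_session_csv(s, file.path(dir, "s1"))
  eeg <- read_eeg_csv(paths[["eeg"]], paths[["events"]])
  expect_equal(eeg$fs, cfg$fs_eeg, tolerance = 1e-6)
  expect_equal(eeg$samples, s$eeg$samples, tolerance = 1e-6)
  expect_equal(eeg$events$stim_hz, 20)
  ph <- read_photometry_csv(paths[["phot"]], induction_s = 100)
  expect_equal(ph$f465, s$photometry$f465, tolerance = 1e-6)
  h <- generate_hypnogram(diag(3), 12, 1, init_state = "NREM")
  hp <- file.path(dir, "hyp.csv")
  write_hypnogram_csv(h, hp)
  expect_identical(read_hypnogram_csv(hp)$states, h$states)
})
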