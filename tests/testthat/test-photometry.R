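test_that("median-anchored detrend removes lines and constants exactly", {
  t <- seq(0, 360 - 0.1, by = 0.1)
  ramp <- 5 + 0.02 * t
  out <- detrend_linear(t, ramp, c(0, 360))
  expect_lt(max(abs(out)), 1e-9 * diff(range(ramp)))
  out2 <- detrend_linear(t, rep(7, length(t)), c(0, 360))
  expect_lt(max(abs(out2)), 1e-12)
  expect_error(detrend_linear(t[1:100], ramp[1:100], c(0, 9.9)), "window")
})

test_that("detrend anchors resist a mid-window transient that tilts a least-squares fit", {
  t <- seq(0, 360 - 0.1, by = 0.1)
  spike <- ifelse(t >= 170 & t < 190, 40, 0)
  x <- 10 + 0.05 * t + spike
  out <- detrend_linear(t, x, c(0, 360))
  # the line is set by the flank medians: flanks go to ~0, spike survives
  expect_lt(abs(median(out[t < 50])), 1e-9)
  expect_lt(abs(median(out[t >= 310])), 1e-9)
  expect_equal(max(out), 40, tolerance = 1e-6)
  # ordinary least squares would tilt: its flank residual medians are biased
  ols <- residuals(lm(x ~ t))
  expect_gt(abs(median(ols[t < 50])), 0.5)
})

test_that("baseline z-score matches its definition and is shift invariant", {
  set.seed(21)
  t <- seq(0, 240 - 0.1, by = 0.1)
  x <- 3 + rnorm(length(t))
  z <- zscore_baseline(t, x, induction_s = 120)
  base <- t >= 60 & t < 120
  expect_equal(mean(z[base]), (mean(x[base]) - median(x[base])) / sd(x[base]),
               tolerance = 1e-12)
  expect_equal(sd(z[base]), 1, tolerance = 1e-12)
  expect_equal(zscore_baseline(t, x + 13.7, 120), z, tolerance = 1e-12)
  # a +5 baseline-SD step after induction reads out ~5 z
  step <- x + ifelse(t >= 120, 5 * sd(x[base]), 0)
  zs <- zscore_baseline(t, step, 120)
  expect_equal(mean(zs[t >= 120]) - mean(z[t >= 120]), 5, tolerance = 1e-9)
  expect_error(zscore_baseline(t, rep(1, length(t)), 120), "degenerate")
  expect_error(zscore_baseline(t[t < 30], x[t < 30], 25), "window")
})

test_that("isosbestic subtraction cancels shared artifacts and keeps the signal", {
  t <- seq(0, 360 - 0.1, by = 0.1)
  ct0 <- motion_correct(t, rep(1.5, length(t)), rep(1.5, length(t)), 180)
  expect_true(all(ct0$z == 0))
  z465 <- sin(t / 10)
  ct1 <- motion_correct(t, z465, numeric(length(t)), 180)
  expect_identical(ct1$z, z465)
  expect_error(motion_correct(t, z465, z465[-1], 180), "alignment")

  # full pipeline on raw channels with known calcium s and shared motion m:
  # motion dominates both baselines, so the z-unit subtraction cancels it
  set.seed(61)
  s <- as.numeric(stats::filter(rnorm(length(t)), 0.9, method = "recursive"))
  s <- s / sd(s) * 0.5
  m <- as.numeric(stats::filter(rnorm(length(t)), 0.3, method = "recursive"))
  m <- m / sd(m) * 5
  bleach <- -0.01 * t
  prec <- photometry_recording(t, 100 + bleach + s + m, 80 + bleach + m,
                               induction_s = 180)
  ct <- correct_photometry(prec)
  expect_lt(abs(cor(ct$z, m)), 0.1)
  expect_gt(cor(ct$z, s), 0.9)
})

test_that("the correction pipeline is invariant to shared affine trends and channel gain", {
  set.seed(9)
  t <- seq(0, 360 - 0.1, by = 0.1)
  s <- as.numeric(stats::filter(rnorm(length(t)), 0.9, method = "recursive"))
  m <- 3 * as.numeric(stats::filter(rnorm(length(t)), 0.7, method = "recursive"))
  f465 <- 100 + s + m + rnorm(length(t), sd = 0.05)
  f405 <- 80 + m + rnorm(length(t), sd = 0.05)
  base <- correct_photometry(photometry_recording(t, f465, f405, 180))$z
  # a shared constant offset cancels exactly
  shifted <- correct_photometry(
    photometry_recording(t, f465 + 12, f405 + 12, 180))$z
  expect_equal(shifted, base, tolerance = 1e-10)
  # a shared linear drift cancels up to flank-median sampling effects
  trend <- 12 - 0.03 * t
  drifted <- correct_photometry(
    photometry_recording(t, f465 + trend, f405 + trend, 180))$z
  expect_lt(max(abs(drifted - base)), 0.1)
  expect_gt(cor(drifted, base), 0.995)
  # positive rescaling of either raw channel is absorbed by the z-score
  scaled <- correct_photometry(
    photometry_recording(t, 2.4 * f465, 0.7 * f405, 180))$z
  expect_equal(scaled, base, tolerance = 1e-8)
})

test_that("epoch activity averages the configured half-open windows", {
  t <- seq(0, 360 - 0.1, by = 0.1)
  ct <- motion_correct(t, numeric(length(t)), numeric(length(t)), 180)
  ea0 <- epoch_activity(ct, seizure_duration_s = 20)
  expect_identical(c(ea0$pre_mean, ea0$during_mean), c(0, 0))
  z <- ifelse(t >= 180 & t < 205, 3, 0)
  ct2 <- motion_correct(t, z, numeric(length(t)), 180)
  ea <- epoch_activity(ct2, seizure_duration_s = 25)
  expect_equal(ea$pre_mean, 0)
  expect_equal(ea$during_mean, 3, tolerance = 1e-9)
  # fallback to the 10-s stimulation window when no after-discharge
  ea_fb <- epoch_activity(ct2, seizure_duration_s = 0)
  expect_equal(ea_fb$during_window, c(180, 190))
  expect_error(epoch_activity(
    motion_correct(t[t > 150], z[t > 150], numeric(sum(t > 150)), 180), 10),
    "window")
})

test_that("corrected pre-seizure mean recovers the generator's latent level", {
  cfg <- quiet_cfg()
  for (sd_ in c(3, 4)) {
    s <- generate_session(cfg, seed = sd_, latent_pre = 1.5)
    ea <- epoch_activity(correct_photometry(s$photometry),
                         seizure_duration_s = s$truth$true_duration)
    expect_equal(ea$pre_mean / cfg$pre_readout_gain, 1.5, tolerance = 0.1)
  }
})
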