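# After-discharge detection fixture: white-noise baseline with a gated
# in-band oscillation after the stimulation train.
make_ad_recording <- function(ad_start_rel, ad_spans, amp = NULL, fs = 1000,
                              dur = 300, induction = 120, stim_s = 10,
                              noise_sd = 5) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), sd = noise_sd)
  # ~10x baseline 4-14 Hz band power unless an amplitude is given
  if (is.null(amp)) amp <- sqrt(2 * 10 * noise_sd^2 * 10 / (fs / 2))
  offset <- induction + stim_s
  for (sp in ad_spans) {
    g <- t >= offset + sp[1] & t < offset + sp[2]
    x[g] <- x[g] + amp * sin(2 * pi * 9 * t[g])
  }
  eeg_recording(x, fs,
                events = data.frame(onset_s = induction, label = "stim",
                                    stim_hz = 20))
}

test_that("after-discharge detection measures a constructed ictal stage", {
  set.seed(51)
  quietr <- make_ad_recording(0, list(), noise_sd = 5)
  out0 <- detect_afterdischarge(quietr, 120)
  expect_false(out0$provoked)
  expect_identical(out0$duration_s, 0)

  burst <- make_ad_recording(0, list(c(0, 28)))
  out <- detect_afterdischarge(burst, 120)
  expect_true(out$provoked)
  expect_lt(abs(out$duration_s - 28), 1.01)

  # a 1.5-s sub-threshold gap is merged into a single ~28-s event
  gap <- make_ad_recording(0, list(c(0, 10), c(11.5, 28)))
  outg <- detect_afterdischarge(gap, 120)
  expect_true(outg$provoked)
  expect_lt(abs(outg$duration_s - 28), 1.01)

  expect_error(detect_afterdischarge(burst, 30), "baseline")
})

test_that("detected durations track ground truth across a low-noise cohort", {
  cfg <- sim_config(noise_sd_eeg = 2)
  coh <- generate_cohort(cfg, 12, seed = 77)
  det <- vapply(coh, function(s) detect_afterdischarge(s$eeg, 180)$duration_s,
                numeric(1))
  tru <- vapply(coh, function(s) s$truth$true_duration, numeric(1))
  expect_gt(cor(det, tru), 0.95)
})

test_that("seizure probability is the exact count ratio with half-up rounding", {
  mk <- function(flags) lapply(flags, function(p)
    structure(list(provoked = p), class = "seizure_outcome"))
  p <- seizure_probability(mk(rep(c(TRUE, FALSE), c(18, 6))))
  expect_equal(p$percent, 75)
  expect_equal(p$percent_int, 75)
  expect_equal(seizure_probability(rep(FALSE, 10))$percent, 0)
  p2 <- seizure_probability(rep(c(TRUE, FALSE), c(6, 12)))
  expect_equal(p2$percent_1dp, 33.3)
  expect_equal(p2$percent_int, 33)
  # half-up rounding, matching percentages quoted to whole numbers
  expect_equal(seizure_probability(rep(c(TRUE, FALSE), c(13, 11)))$percent_int, 54)
  # permutation invariance
  set.seed(52)
  flags <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(seizure_probability(flags)$percent,
               seizure_probability(sample(flags))$percent)
  expect_error(seizure_probability(logical(0)), "empty")
})

test_that("fragmentation index equals bouts over epochs", {
  h1 <- hypnogram(rep("Wake", 10))
  f1 <- fragmentation_index(h1, "Wake")
  expect_equal(f1$n_bouts, 1L)
  expect_equal(f1$index, 0.1)
  h2 <- hypnogram(rep(c("Wake", "NREM"), 10))
  expect_equal(fragmentation_index(h2, "Wake")$index, 1.0)
  h3 <- hypnogram(c("Wake", "Wake", "Wake", "NREM", "NREM", "Wake"))
  f3 <- fragmentation_index(h3, "Wake")
  expect_equal(f3$n_bouts, 2L)
  expect_equal(f3$n_epochs, 4L)
  expect_equal(f3$index, 0.5)
  # absent state is flagged, not reported as zero
  fr <- fragmentation_index(h3, "REM")
  expect_false(fr$defined)
  expect_true(is.na(fr$index))
})

test_that("merging adjacent bouts never increases the fragmentation index", {
  set.seed(53)
  for (k in 1:25) {
    st <- random_states(60)
    h <- hypnogram(st)
    r <- rle(st)
    # relabel a separating epoch to merge two same-state bouts, where possible
    pos <- which(r$values[-c(1, length(r$values))] != "Wake" &
                   r$lengths[-c(1, length(r$values))] == 1)
    for (i in pos) {
      j <- i + 1L  # run index of the separator
      if (r$values[j - 1L] == "Wake" && r$values[j + 1L] == "Wake") {
        idx <- cumsum(r$lengths)[j]
        st2 <- st; st2[idx] <- "Wake"
        before <- fragmentation_index(h, "Wake")$index
        after <- fragmentation_index(hypnogram(st2), "Wake")$index
        expect_lte(after, before)
      }
    }
    # boundary characterizations
    fw <- fragmentation_index(h, "Wake")
    if (fw$defined) {
      lens <- r$lengths[r$values == "Wake"]
      expect_equal(fw$index == 1, all(lens == 1))
      expect_equal(fw$index == 1 / fw$n_epochs, length(lens) == 1)
    }
  }
})

test_that("state percentages match epoch counting and sum to 100", {
  h <- hypnogram(rep("Wake", 8))
  expect_equal(state_percentages(h),
               c(Wake = 100, NREM = 0, REM = 0))
  h2 <- hypnogram(rep(c("Wake", "NREM"), each = 5))
  expect_equal(unname(state_percentages(h2)), c(50, 50, 0))
  set.seed(54)
  st <- random_states(200)
  h3 <- hypnogram(st)
  mask <- seq_len(120)
  p <- state_percentages(h3, mask)
  for (s in c("Wake", "NREM", "REM")) {
    expect_equal(p[[s]], 100 * sum(st[mask] == s) / 120)
  }
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_error(state_percentages(h3, integer(0)), "empty")
})

test_that("sucrose preference is the consumed ratio", {
  expect_equal(sucrose_preference(3, 4), 0.75)
  expect_equal(sucrose_preference(2, 4), 0.5)
  expect_equal(sucrose_preference(0, 4), 0)
  expect_error(sucrose_preference(5, 4), "sucrose_consumed")
  expect_error(sucrose_preference(1, 0), "total_consumed")
})
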