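# Synthetic cohort generator: determinism, occupancy recovery, signal model.

test_that("degenerate all-WAKE profile yields an all-WAKE hypnogram", {
  spec <- cohort_spec(n_mice = 1, days = 1, seed = 3,
                      stage_profile = pure_stage_profile("WAKE"))
  hyp <- generate_hypnogram(spec, 0)
  expect_equal(hyp$n_epochs, 8640L)
  expect_true(all(hyp$stages == "WAKE"))
})

test_that("hypnogram generation is deterministic and differs across mice", {
  spec <- cohort_spec(n_mice = 2, days = 1, seed = 42)
  h1 <- generate_hypnogram(spec, 0)
  h2 <- generate_hypnogram(spec, 0)
  expect_identical(h1$stages, h2$stages)
  h_other <- generate_hypnogram(spec, 1)
  expect_false(identical(h1$stages, h_other$stages))
})

test_that("empirical hourly WAKE occupancy tracks the injected curve", {
  # 20 replicate mice, 3 days each; the mean hourly WAKE fraction should
  # correlate strongly with the injected profile
  spec <- cohort_spec(n_mice = 20, days = 3, seed = 7)
  frac <- matrix(0, 24, spec$n_mice)
  for (i in seq_len(spec$n_mice)) {
    hyp <- generate_hypnogram(spec, i - 1L)
    zt_hour <- floor(epoch_zt(hyp))
    frac[, i] <- tapply(hyp$stages == "WAKE", zt_hour, mean)
  }
  injected <- spec$stage_profile[, "WAKE"]
  expect_gt(cor(rowMeans(frac), injected), 0.8)
  # occupancy matches in level, not only shape
  expect_lt(max(abs(rowMeans(frac) - injected)), 0.1)
})

test_that("invalid cohort specifications are rejected", {
  bad_profile <- default_stage_profile()
  bad_profile[3, ] <- c(0.5, 0.4, 0.2)  # sums to 1.1
  expect_error(cohort_spec(n_mice = 1, stage_profile = bad_profile),
               "summing to 1")
  mm <- default_modulation_map()
  mm$a[5, "NREM"] <- 1.2
  expect_error(cohort_spec(n_mice = 1, modulation_map = mm), "\\[0, 1\\)")
})

test_that("epoch signals are deterministic, finite, and mean free", {
  spec <- flat_spec(n_mice = 1, days = 1, seed = 9)
  hyp <- generate_hypnogram(spec, 0)
  rec1 <- generate_epoch_signals(spec, hyp, 0)
  rec2 <- generate_epoch_signals(spec, hyp, 0)
  expect_identical(rec1$eeg, rec2$eeg)
  expect_identical(rec1$emg, rec2$emg)
  expect_true(all(is.finite(rec1$eeg)))
  v <- apply(rec1$eeg[, 1:50], 2, var)
  expect_true(all(v > 0))
  expect_lt(max(abs(colMeans(rec1$eeg[, 1:50]))), 1e-10)
})

test_that("without modulation the hourly mean power is time constant", {
  spec <- flat_spec(n_mice = 1, days = 1, seed = 13,
                    stage_profile = pure_stage_profile("NREM"))
  hyp <- generate_hypnogram(spec, 0)
  rec <- generate_epoch_signals(spec, hyp, 0)
  sp <- epoch_spectra(rec$eeg, rec$fs)
  hss <- hourly_stage_spectra(sp, hyp)
  hourly <- hss$power[, "NREM", ]
  cv <- apply(hourly, 2, function(x) sd(x) / mean(x))
  # per-epoch periodograms equal the template by construction, so hourly
  # means are essentially constant; allow generous slack below the 0.1 bound
  expect_lt(max(cv[-1]), 0.1)
})

test_that("WAKE and NREM EMG amplitudes separate almost perfectly", {
  spec <- cohort_spec(n_mice = 1, days = 1, seed = 17)
  hyp <- generate_hypnogram(spec, 0)
  rec <- generate_epoch_signals(spec, hyp, 0)
  amps <- emg_amplitude(rec)
  w <- amps[hyp$stages == "WAKE"]
  n <- amps[hyp$stages == "NREM"]
  # AUC via the rank-sum statistic
  r <- rank(c(w, n))
  auc <- (sum(r[seq_along(w)]) - length(w) * (length(w) + 1) / 2) /
    (length(w) * length(n))
  expect_gt(auc, 0.95)
})

test_that("cohort generation honours size and the seeding contract", {
  spec0 <- cohort_spec(n_mice = 0, days = 1, seed = 1)
  expect_length(generate_cohort(spec0)$mice, 0)
  spec <- cohort_spec(n_mice = 2, days = 1, seed = 5)
  c1 <- generate_cohort(spec, keep_signals = FALSE)
  c2 <- generate_cohort(spec, keep_signals = FALSE)
  expect_false(identical(c1$mice[[1]]$hypnogram$stages,
                         c1$mice[[2]]$hypnogram$stages))
  expect_identical(c1$mice[[1]]$hypnogram$stages, c2$mice[[1]]$hypnogram$stages)
  expect_identical(c1$mice[[2]]$hypnogram$stages, c2$mice[[2]]$hypnogram$stages)
  expect_named(c1$truth, c("modulation", "hourly_profile"))
})

test_that("single-mouse pipeline recovers an injected modulation", {
  spec <- single_freq_spec(a = 0.3, p = 18, stage = "NREM", freq = 4,
                           days = 3, seed = 29)
  hyp <- generate_hypnogram(spec, 0)
  rec <- generate_epoch_signals(spec, hyp, 0)
  hss <- hourly_stage_spectra(epoch_spectra(rec$eeg, rec$fs), hyp)
  rc <- rhythm_components(hss)
  at4 <- rc[rc$stage == "NREM" & abs(rc$freq_hz - 4) < 0.05, ]
  expect_equal(at4$amplitude, 0.3, tolerance = 0.05 / 0.3)
  expect_lt(abs(circ_diff(at4$peak_zt, 18)), 1)
  # frequencies far from the injected one carry no rhythm
  far <- rc[rc$stage == "NREM" & abs(rc$freq_hz - 10) < 0.05, ]
  expect_lt(far$amplitude, 0.05)
})

test_that("aging attenuates amplitude and delays phase in the spec", {
  young <- cohort_spec(n_mice = 1, seed = 1)
  old <- apply_aging(young, attenuation = 0.5, delay = 2)
  f <- spectral_freqs()
  i4 <- which.min(abs(f - 4))
  expect_equal(old$modulation_map$a[i4, "NREM"], 0.15)
  expect_equal(old$modulation_map$p[i4, "NREM"], 20)
  # stage profile keeps valid probabilities and unit row sums
  expect_true(all(abs(rowSums(old$stage_profile) - 1) < 1e-9))
  expect_true(all(old$stage_profile >= 0))
  # deviation amplitude halves
  dev_y <- young$stage_profile[, "WAKE"] - mean(young$stage_profile[, "WAKE"])
  dev_o <- old$stage_profile[, "WAKE"] - mean(old$stage_profile[, "WAKE"])
  expect_equal(max(abs(dev_o)) / max(abs(dev_y)), 0.5, tolerance = 0.02)
})
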