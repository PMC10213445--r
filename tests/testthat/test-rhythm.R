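# Relative normalization, first-harmonic extraction, cosinor, circular mean.

# build an hourly_stage_spectra holding given NREM series (other stages empty)
hss_from_series <- function(series_matrix, freqs = NULL) {
  n_hours <- nrow(series_matrix)
  nf <- ncol(series_matrix)
  if (is.null(freqs)) freqs <- seq_len(nf) * 0.1
  power <- array(NA_real_, c(n_hours, 3, nf),
                 dimnames = list(NULL, STAGES, sprintf("%.1f", freqs)))
  power[, "NREM", ] <- series_matrix
  n_ep <- matrix(0L, n_hours, 3, dimnames = list(NULL, STAGES))
  n_ep[, "NREM"] <- ifelse(is.na(series_matrix[, 1]), 0L, 1L)
  structure(
    list(power = power, n_epochs = n_ep, freqs = freqs,
         zt = (seq_len(n_hours) - 1) %% 24, epoch_s = 10),
    class = "hourly_stage_spectra"
  )
}

test_that("normalization gives zero-mean relative deviations", {
  const <- hss_from_series(matrix(5, 24, 2))
  np <- suppressWarnings(normalize_power(const))
  expect_true(all(np$norm[, "NREM", ] == 0))
  two <- hss_from_series(matrix(c(rep(1, 12), rep(3, 12)), 24, 1))
  np2 <- suppressWarnings(normalize_power(two))
  expect_equal(unname(np2$norm[, "NREM", 1]),
               c(rep(-0.5, 12), rep(0.5, 12)))
  arb <- hss_from_series(matrix(withr::with_seed(11, rexp(48 * 3, 0.2)), 48))
  np3 <- suppressWarnings(normalize_power(arb))
  expect_lt(max(abs(colMeans(np3$norm[, "NREM", ]))), 1e-12)
})

test_that("normalization respects missing hours and prerequisites", {
  m <- matrix(withr::with_seed(12, rexp(72)), 72, 1)
  m[c(5, 40), 1] <- NA
  np <- suppressWarnings(normalize_power(hss_from_series(m)))
  expect_true(all(is.na(np$norm[c(5, 40), "NREM", 1])))
  mu <- mean(m[, 1], na.rm = TRUE)
  expect_equal(unname(np$norm[1, "NREM", 1]), (m[1, 1] - mu) / mu)
  expect_identical(unname(np$n_hours_used["NREM", 1]), 70L)
  short <- hss_from_series(matrix(rexp(12), 12, 1))
  expect_error(normalize_power(short, strict = TRUE), "non-missing hour")
  expect_warning(normalize_power(short), "dropped")
})

test_that("the first harmonic of a 24-h cosine is recovered exactly", {
  i <- 1:72
  x <- 0.3 * cos(2 * pi * (i - 18) / 24)
  cs <- fourier_component(x)
  ap <- amplitude_peaktime(cs)
  expect_equal(ap[["amplitude"]], 0.3, tolerance = 1e-12)
  expect_equal(ap[["peak"]], 18, tolerance = 1e-9)
  # orthogonal 12-h harmonic projects to zero
  cs12 <- fourier_component(cos(2 * pi * i / 12))
  expect_lt(abs(cs12[["cos"]]), 1e-12)
  expect_lt(abs(cs12[["sin"]]), 1e-12)
  zero <- fourier_component(rep(0, 72))
  expect_equal(unname(zero), c(0, 0))
})

test_that("missing hours reduce T' without biasing the estimate", {
  i <- 1:72
  x <- 0.4 * cos(2 * pi * (i - 6) / 24)
  x[c(3, 30, 55)] <- NA
  ap <- amplitude_peaktime(fourier_component(x))
  expect_equal(ap[["amplitude"]], 0.4, tolerance = 0.05)
  expect_lt(abs(circ_diff(ap[["peak"]], 6)), 0.3)
})

test_that("amplitude and peak time follow the two-argument arctangent", {
  expect_equal(amplitude_peaktime(c(cos = 1, sin = 0)),
               c(amplitude = 1, peak = 0))
  expect_equal(amplitude_peaktime(c(cos = 0, sin = 1)),
               c(amplitude = 1, peak = 6))
  expect_equal(amplitude_peaktime(c(cos = 0, sin = -1)),
               c(amplitude = 1, peak = 18))
  res <- amplitude_peaktime(c(cos = 0, sin = 0))
  expect_equal(res[["amplitude"]], 0)
  expect_true(is.na(res[["peak"]]))
})

test_that("rotation of a complete series rotates the peak, not the amplitude", {
  i <- 1:72
  base <- 0.25 * cos(2 * pi * (i - 10) / 24) + 0.05 * cos(2 * pi * i / 8)
  ref <- amplitude_peaktime(fourier_component(base))
  for (k in c(1, 5, 13, 23)) {
    rotated <- base[((i - 1 + k) %% 72) + 1]   # shift by k hours
    got <- amplitude_peaktime(fourier_component(rotated))
    expect_equal(got[["amplitude"]], ref[["amplitude"]], tolerance = 1e-9)
    expect_lt(abs(circ_diff(got[["peak"]], wrap_time(ref[["peak"]] - k))), 1e-9)
  }
})

test_that("cosinor fit is exact on a noiseless representable series", {
  t <- 0:71
  y <- 5 + 2 * cos(2 * pi * (t - 20) / 24)
  fit <- cosinor_fit(y, t)
  expect_true(fit$converged)
  expect_equal(fit$mesor, 5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 2, tolerance = 1e-6)
  expect_equal(fit$acrophase, 20, tolerance = 1e-6)
  expect_equal(fit$period, 24, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("cosinor flags an unidentifiable constant series", {
  fit <- cosinor_fit(rep(3, 24))
  expect_true(fit$flat)
  expect_equal(fit$amplitude, 0)
  expect_true(is.na(fit$period))
})

test_that("cosinor recovers amplitude and phase under noise", {
  t <- 0:71
  ok_amp <- 0; ok_phi <- 0; n_rep <- 100
  withr::with_seed(13, {
    for (r in seq_len(n_rep)) {
      y <- 5 + 2 * cos(2 * pi * (t - 20) / 24) + rnorm(72, 0, 0.2)
      fit <- cosinor_fit(y, t)
      if (abs(fit$amplitude - 2) <= 0.15) ok_amp <- ok_amp + 1
      if (abs(circ_diff(fit$acrophase, 20)) <= 0.5) ok_phi <- ok_phi + 1
    }
  })
  expect_gte(ok_amp / n_rep, 0.95)
  expect_gte(ok_phi / n_rep, 0.95)
})

test_that("cosinor and the harmonic estimator agree on noiseless cosines", {
  for (p in c(0, 7.3, 18)) {
    i <- 1:72
    y <- 1 + 0.5 * cos(2 * pi * (i - p) / 24)
    harm <- amplitude_peaktime(fourier_component(y - mean(y)))
    fit <- cosinor_fit(y, t = i)
    expect_lt(abs(circ_diff(fit$acrophase, harm[["peak"]])), 1e-6)
  }
})

test_that("circular mean handles wraparound and antipodal inputs", {
  expect_equal(circular_mean(c(6, 6, 6)), 6)
  expect_equal(circular_mean(c(23, 1)), 0)
  expect_true(is.na(circular_mean(c(0, 12))))
  expect_error(circular_mean(numeric(0)), "nonempty")
})
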