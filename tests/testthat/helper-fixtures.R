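# Shared fixture builders. All synthetic inputs are generated in code with
# fixed seeds; nothing is read from disk.

# cohort spec whose modulation map is zero except a single (stage, freq) cell
single_freq_spec <- function(a = 0.3, p = 18, stage = "NREM", freq = 4,
                             n_mice = 1, days = 3, seed = 11L, ...) {
  f <- spectral_freqs()
  zero <- matrix(0, length(f), 3, dimnames = list(sprintf("%.1f", f), STAGES))
  mm <- list(a = zero, p = zero)
  mm$a[which.min(abs(f - freq)), stage] <- a
  mm$p[which.min(abs(f - freq)), stage] <- p
  cohort_spec(n_mice = n_mice, days = days, seed = seed,
              modulation_map = mm, ...)
}

# cohort spec with no circadian modulation at all
flat_spec <- function(n_mice = 1, days = 3, seed = 21L, ...) {
  single_freq_spec(a = 0, p = 0, n_mice = n_mice, days = days, seed = seed, ...)
}

# degenerate stage profile: probability 1 for one stage at every hour
pure_stage_profile <- function(stage = "WAKE") {
  out <- matrix(0, 24, 3, dimnames = list(0:23, STAGES))
  out[, stage] <- 1
  out
}

# hand-made phase_features object for regressor tests that need analytic
# control over the feature -> time mapping
make_phase_features <- function(X, zt, mode = "all_stages") {
  if (is.null(colnames(X))) colnames(X) <- paste0("NREM_", seq_len(ncol(X)))
  structure(
    list(
      features = X, zt = zt, hour = seq_along(zt) - 1L,
      imputed = rep(FALSE, length(zt)), mode = mode, freqs = seq_len(ncol(X))
    ),
    class = "phase_features"
  )
}

# smooth injective analytic map from ZT to a feature vector: two harmonics
# passed through mild nonlinearities, plus optional Gaussian noise
analytic_mouse_features <- function(hours = 72, noise_sd = 0, seed = 1L,
                                    zt0 = 0, phase_shift = 0) {
  set.seed(seed)
  zt <- (zt0 + seq_len(hours) - 1) %% 24
  ang <- (zt - phase_shift) / 24 * 2 * pi
  base <- cbind(
    cos(ang), sin(ang), cos(ang)^2, exp(0.5 * sin(ang)),
    cos(2 * ang), sin(2 * ang)
  )
  X <- base + matrix(rnorm(length(base), 0, noise_sd), nrow(base))
  colnames(X) <- paste0("NREM_", seq_len(ncol(X)))
  make_phase_features(X, zt)
}

# brute-force Otsu oracle: exhaustive scan over all bin boundaries using
# plain loops over the histogram
otsu_oracle <- function(values, n_bins = 256L) {
  x <- values[!is.na(values)]
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / n_bins
  bin <- pmin(pmax(floor((x - lo) / width) + 1, 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  bcv <- rep(-Inf, n_bins - 1L)
  for (j in seq_len(n_bins - 1L)) {
    c0 <- counts[1:j]; c1 <- counts[(j + 1):n_bins]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * centers[1:j]) / w0
    mu1 <- sum(c1 * centers[(j + 1):n_bins]) / w1
    bcv[j] <- w0 * w1 * (mu0 - mu1)^2
  }
  # same tie rule as the implementation: mean of maximizing boundaries
  lo + mean(which(bcv >= max(bcv) * (1 - 1e-10))) * width
}
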