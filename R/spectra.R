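# Per-epoch EEG power spectra on the fixed 0-16 Hz / 0.1 Hz grid and their
# stage-conditioned hourly averages.

#' Power spectrum of one epoch
#'
#' One-sided magnitude-squared Fourier spectrum of a single epoch,
#' rectangular window, with only the epoch mean removed. The per-bin power
#' convention is `|Y_k|^2 / n` with interior bins doubled, so that the sum
#' of the full one-sided spectrum equals epoch variance (population
#' convention) times `n` (Parseval). With 10-s epochs at 128 Hz the native
#' resolution is exactly 0.1 Hz and the spectrum is returned on the 0--16 Hz
#' analysis grid without any interpolation; inputs whose native grid does
#' not contain 0.1 Hz steps are rejected.
#'
#' @param x numeric vector of epoch samples (1280 for the default layout).
#' @param fs sampling rate in Hz.
#' @param fmax upper frequency bound in Hz (default 16); `NULL` returns the
#'   full one-sided spectrum up to Nyquist.
#' @return numeric vector of per-bin power with attribute `freqs` (Hz);
#'   161 bins at the defaults.
#' @export
epoch_power_spectrum <- function(x, fs, fmax = 16) {
  n <- length(x)
  if (n < 2) stop("epoch too short")
  df <- fs / n
  step <- 0.1 / df
  if (abs(step - round(step)) > 1e-9)
    stop("0.1 Hz is not a native frequency bin for length ", n, " at ", fs, " Hz")
  y <- stats::fft(x - mean(x))
  half <- floor(n / 2)
  p <- Mod(y[1:(half + 1)])^2 / n
  if (n %% 2 == 0) p[2:half] <- 2 * p[2:half] else p[2:(half + 1)] <- 2 * p[2:(half + 1)]
  freqs <- (0:half) * df
  if (!is.null(fmax)) {
    if (fmax > freqs[length(freqs)] + 1e-12)
      stop("fmax exceeds the Nyquist frequency")
    keep <- seq(1L, round(fmax / 0.1) * round(step) + 1L, by = round(step))
    p <- p[keep]; freqs <- freqs[keep]
  }
  structure(p, freqs = freqs)
}

#' Power spectra for all epochs of a recording
#'
#' Applies [epoch_power_spectrum()] to every epoch, batched through a single
#' multivariate FFT.
#'
#' @param eeg EEG sample matrix (samples x epochs).
#' @param fs sampling rate in Hz.
#' @param fmax upper frequency bound (default 16 Hz).
#' @return matrix epochs x frequency bins with attribute `freqs`.
#' @export
epoch_spectra <- function(eeg, fs, fmax = 16) {
  eeg <- as.matrix(eeg)
  n <- nrow(eeg)
  df <- fs / n
  step <- 0.1 / df
  if (abs(step - round(step)) > 1e-9)
    stop("0.1 Hz is not a native frequency bin for length ", n, " at ", fs, " Hz")
  keep <- seq(1L, round(fmax / 0.1) * round(step) + 1L, by = round(step))
  half <- floor(n / 2)
  if (max(keep) > half + 1) stop("fmax exceeds the Nyquist frequency")
  y <- stats::mvfft(sweep(eeg, 2, colMeans(eeg)))
  p <- Mod(y[keep, , drop = FALSE])^2 / n
  interior <- keep > 1 & keep < (half + 1)
  p[interior, ] <- 2 * p[interior, ]
  structure(t(p), freqs = (keep - 1) * df)
}

#' Hourly stage-conditioned spectral tensor
#'
#' Averages per-epoch spectra within each (recording hour, stage) cell. A
#' cell in which the stage never occurs is masked (`NA` power, 0 epochs);
#' downstream analyses treat masked cells as absent, never as zero.
#'
#' @param spectra epochs x frequency matrix from [epoch_spectra()] (or a
#'   list of [epoch_power_spectrum()] vectors).
#' @param hyp the aligned [hypnogram()].
#' @return object of class `hourly_stage_spectra`: list with `power`
#'   (array hour x stage x frequency), `n_epochs` (hour x stage), `freqs`,
#'   `zt` (hour-start ZT), `epoch_s`.
#' @export
hourly_stage_spectra <- function(spectra, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (is.list(spectra)) spectra <- do.call(rbind, spectra)
  if (nrow(spectra) != hyp$n_epochs)
    stop("spectra and hypnogram have different epoch counts")
  per_hour <- 3600 / hyp$epoch_s
  if (hyp$n_epochs %% per_hour != 0)
    stop("recording must cover a whole number of hours")
  n_hours <- hyp$n_epochs / per_hour
  freqs <- attr(spectra, "freqs")
  if (is.null(freqs)) freqs <- spectral_freqs()[seq_len(ncol(spectra))]
  hour <- rep(seq_len(n_hours), each = per_hour)
  power <- array(
    NA_real_, dim = c(n_hours, 3L, ncol(spectra)),
    dimnames = list(NULL, STAGES, sprintf("%.1f", freqs))
  )
  n_ep <- matrix(0L, n_hours, 3L, dimnames = list(NULL, STAGES))
  for (s in seq_along(STAGES)) {
    sel <- hyp$stages == STAGES[s]
    if (!any(sel)) next
    cnt <- tabulate(hour[sel], nbins = n_hours)
    sums <- rowsum(spectra[sel, , drop = FALSE], hour[sel])
    rows <- as.integer(rownames(sums))
    power[rows, s, ] <- sums / cnt[rows]
    n_ep[, s] <- cnt
  }
  structure(
    list(
      power = power, n_epochs = n_ep, freqs = freqs,
      zt = wrap_time(hyp$zt0_offset + seq_len(n_hours) - 1L),
      epoch_s = hyp$epoch_s
    ),
    class = "hourly_stage_spectra"
  )
}

#' @export
print.hourly_stage_spectra <- function(x, ...) {
  miss <- sum(x$n_epochs == 0)
  cat(sprintf(
    "<hourly_stage_spectra> %d h x %d stages x %d bins; %d masked cell(s)\n",
    dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], miss
  ))
  invisible(x)
}

#' Pool an hourly tensor across stages
#'
#' Epoch-count-weighted mean over stages per hour, i.e. the hourly spectrum
#' that ignores sleep--wake staging.
#'
#' @param hss an `hourly_stage_spectra`.
#' @return matrix hour x frequency with attribute `freqs`.
#' @export
pool_stages <- function(hss) {
  stopifnot(inherits(hss, "hourly_stage_spectra"))
  n_hours <- dim(hss$power)[1]
  out <- matrix(NA_real_, n_hours, length(hss$freqs))
  for (i in seq_len(n_hours)) {
    w <- hss$n_epochs[i, ]
    if (sum(w) == 0) next
    cell <- hss$power[i, , , drop = TRUE]
    out[i, ] <- colSums(cell * w, na.rm = TRUE) / sum(w)
  }
  structure(out, freqs = hss$freqs)
}

#' Normalize a spectrum to a unit-sum distribution
#'
#' Divides a power spectrum by the sum of its densities so it can be treated
#' as a distribution over frequency; the shape is preserved and any overall
#' scale (amplifier gain, electrode impedance) cancels.
#'
#' @param p nonnegative power values.
#' @return values summing to 1.
#' @export
normalize_distribution <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) stop("power must be finite and nonnegative")
  s <- sum(p)
  if (s <= 0) stop("cannot normalize an all-zero spectrum")
  p / s
}
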