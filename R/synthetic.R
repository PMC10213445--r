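# Synthetic cohort generator: hypnograms from a time-inhomogeneous Markov
# chain, EEG epochs from random-phase inverse FFT of circadian-modulated
# spectral templates, EMG epochs from a per-stage log-normal amplitude model.

# Mean bout durations (seconds) used to turn hourly occupancy targets into
# transition probabilities. Stand-ins for unreported animal statistics.
BOUT_SECONDS <- c(WAKE = 60, NREM = 100, REM = 30)

# Build a 3x3 epoch-to-epoch transition matrix with stationary distribution
# `pi_target` and mean bout lengths `d_epochs` (in epochs), via a symmetric
# probability-flow construction: F[s,t] = pi_s P[s,t] symmetric with row sums
# w_s = pi_s/d_s. Feasibility (F >= 0) requires each leave-rate w_s to be at
# most the sum of the others and at most pi_s; infeasible targets are
# repaired by scaling rates, which preserves the stationary distribution
# exactly and only shortens minority-stage bouts.
stage_transition_matrix <- function(pi_target, d_epochs) {
  stopifnot(length(pi_target) == 3L, abs(sum(pi_target) - 1) < 1e-9)
  w <- ifelse(pi_target > 0, pi_target / d_epochs, 0)
  w <- pmin(w, pi_target)           # self-transition prob must be >= 0
  for (s in 1:3) {                  # triangle repair: at most one violator
    others <- sum(w[-s])
    if (w[s] > others) {
      if (others == 0) w[s] <- 0 else {
        w[-s] <- pmin(w[-s] * (w[s] / others), pi_target[-s])
        w[s] <- min(w[s], sum(w[-s]))
      }
    }
  }
  Fm <- matrix(0, 3, 3)
  Fm[1, 2] <- Fm[2, 1] <- (w[1] + w[2] - w[3]) / 2
  Fm[1, 3] <- Fm[3, 1] <- (w[1] - w[2] + w[3]) / 2
  Fm[2, 3] <- Fm[3, 2] <- (-w[1] + w[2] + w[3]) / 2
  Fm[Fm < 0] <- 0
  P <- matrix(0, 3, 3, dimnames = list(STAGES, STAGES))
  for (s in 1:3) {
    if (pi_target[s] <= 0) { P[s, s] <- 1; next }
    P[s, -s] <- Fm[s, -s] / pi_target[s]
    P[s, s] <- max(0, 1 - sum(P[s, -s]))
    P[s, ] <- P[s, ] / sum(P[s, ])
  }
  P
}

#' Generate a synthetic hypnogram
#'
#' Simulates one mouse's per-epoch stage sequence from a time-inhomogeneous
#' Markov chain whose stationary occupancy in each ZT hour matches the
#' spec's stage-occupancy profile, with stage persistence set by fixed mean
#' bout durations (WAKE 60 s, NREM 100 s, REM 30 s). Deterministic given the
#' spec seed and mouse index.
#'
#' @param spec a [cohort_spec()].
#' @param mouse_index 0-based mouse index within the cohort.
#' @return a [hypnogram()] covering `spec$days` days.
#' @export
generate_hypnogram <- function(spec, mouse_index = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_epochs <- as.integer(3600 * 24 * spec$days / spec$epoch_s)
  d_epochs <- BOUT_SECONDS[STAGES] / spec$epoch_s
  zt <- wrap_time(spec$zt0_offset + (seq_len(n_epochs) - 1) * spec$epoch_s / 3600)
  hour_of_day <- floor(zt) %% 24
  P_by_hour <- lapply(0:23, function(h)
    stage_transition_matrix(spec$stage_profile[h + 1, STAGES], d_epochs))
  set.seed(mouse_seed(spec$seed, mouse_index, stream = 1L))
  stages <- integer(n_epochs)
  u <- runif(n_epochs)
  p0 <- spec$stage_profile[hour_of_day[1] + 1, STAGES]
  stages[1] <- findInterval(u[1], cumsum(p0), left.open = TRUE) + 1L
  for (k in 2:n_epochs) {
    pr <- P_by_hour[[hour_of_day[k] + 1]][stages[k - 1], ]
    stages[k] <- findInterval(u[k], cumsum(pr), left.open = TRUE) + 1L
  }
  hypnogram(STAGES[stages], epoch_s = spec$epoch_s, zt0_offset = spec$zt0_offset)
}

# One-sided target power for every epoch of one stage at its ZT:
# template * (1 + a cos(2 pi (t - p)/24)); rows = frequency bins, cols = epochs
modulated_power <- function(spec, stage, zt) {
  tmpl <- spec$spectral_template[, stage]
  a <- spec$modulation_map$a[, stage]
  p <- spec$modulation_map$p[, stage]
  ph <- outer(p, zt, function(pp, tt) cos(2 * pi * (tt - pp) / 24))
  tmpl * (1 + a * ph)
}

#' Synthesize per-epoch EEG and EMG signals
#'
#' EEG: each 10-s epoch is the inverse Fourier transform of the epoch
#' stage's spectral template, multiplied per frequency by the circadian
#' factor `1 + a*cos(2*pi*(t - p)/24)` at the epoch's ZT `t`, with
#' independent uniform random phases per epoch and frequency; the DC
#' coefficient is zero (epochs are mean free) and no power is placed above
#' 16 Hz. By construction the per-epoch periodogram equals the modulated
#' template exactly, so recovery tolerances downstream are tight. EMG: white
#' noise whose per-epoch SD is drawn from the stage's log10-normal amplitude
#' model. Deterministic given the spec seed and mouse index.
#'
#' @param spec a [cohort_spec()].
#' @param hypnogram a [hypnogram()] consistent with `spec`.
#' @param mouse_index 0-based mouse index (selects the seed stream).
#' @return an `epoched_recording`: list with `eeg` and `emg` sample matrices
#'   (samples x epochs), `fs`, and `epoch_s`.
#' @export
generate_epoch_signals <- function(spec, hypnogram, mouse_index = 0L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(hypnogram, "hypnogram"))
  n_epochs <- hypnogram$n_epochs
  expected <- as.integer(3600 * 24 * spec$days / spec$epoch_s)
  if (n_epochs != expected)
    stop("hypnogram length inconsistent with spec: ", n_epochs, " vs ", expected)
  n <- as.integer(spec$fs * spec$epoch_s)
  nf <- length(spectral_freqs())           # bins 0 .. 16 Hz
  zt <- epoch_zt(hypnogram)
  set.seed(mouse_seed(spec$seed, mouse_index, stream = 2L))
  eeg <- matrix(0, n, n_epochs)
  chunk <- as.integer(3600 / spec$epoch_s) # one hour of epochs at a time
  for (start in seq(1L, n_epochs, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_epochs)
    Smat <- matrix(0, nf, length(idx))
    for (stage in STAGES) {
      sel <- hypnogram$stages[idx] == stage
      if (any(sel)) Smat[, sel] <- modulated_power(spec, stage, zt[idx][sel])
    }
    # complex spectrum: |Y_k|^2 = n * S_k / 2 at interior bins, DC = 0
    mod <- sqrt(n * Smat[-1, , drop = FALSE] / 2)
    ph <- runif(length(mod), 0, 2 * pi)
    Y <- matrix(0 + 0i, n, length(idx))
    Y[2:nf, ] <- complex(real = mod * cos(ph), imaginary = mod * sin(ph))
    Y[n + 2 - (2:nf), ] <- Conj(Y[2:nf, ])
    eeg[, idx] <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  }
  log_amp <- rnorm(
    n_epochs,
    mean = spec$emg_params[hypnogram$stages, "mean"],
    sd = spec$emg_params[hypnogram$stages, "sd"]
  )
  emg <- rnorm(n * n_epochs)
  dim(emg) <- c(n, n_epochs)
  emg <- emg * rep(10^log_amp, each = n)
  structure(
    list(eeg = eeg, emg = emg, fs = spec$fs, epoch_s = spec$epoch_s),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf(
    "<epoched_recording> %d epochs of %gs at %g Hz (EEG + EMG)\n",
    ncol(x$eeg), x$epoch_s, x$fs
  ))
  invisible(x)
}

#' Injected ground truth for a cohort specification
#'
#' Collects the quantities the analysis pipeline is supposed to recover from
#' a synthetic cohort: the injected per-stage, per-frequency modulation
#' amplitude and peak time, and the injected hourly stage-occupancy curves.
#'
#' @param spec a [cohort_spec()].
#' @return list with `modulation` (tibble: stage, freq_hz, a, p) and
#'   `hourly_profile` (24 x 3 matrix).
#' @export
synthetic_truth <- function(spec) {
  f <- spectral_freqs()
  mod <- tibble::tibble(
    stage = rep(STAGES, each = length(f)),
    freq_hz = rep(f, 3L),
    a = c(spec$modulation_map$a[, STAGES]),
    p = c(spec$modulation_map$p[, STAGES])
  )
  list(modulation = mod, hourly_profile = spec$stage_profile)
}

#' Generate a full synthetic cohort
#'
#' Generates `spec$n_mice` independent mice. Per-mouse seed streams are
#' derived from the cohort root seed and the mouse index, so any one mouse
#' can be regenerated on its own and reruns are bit identical.
#'
#' @param spec a [cohort_spec()].
#' @param keep_signals if `FALSE`, omit the (large) raw signal matrices and
#'   return only hypnograms; use [cohort_hourly_spectra()] for a
#'   memory-bounded spectral analysis of big cohorts.
#' @return list with elements `mice` (list of per-mouse lists holding
#'   `hypnogram` and optionally `recording`) and `truth`
#'   (see [synthetic_truth()]).
#' @export
generate_cohort <- function(spec, keep_signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  mice <- lapply(seq_len(spec$n_mice) - 1L, function(i) {
    hyp <- generate_hypnogram(spec, i)
    m <- list(mouse = i, hypnogram = hyp)
    if (keep_signals) m$recording <- generate_epoch_signals(spec, hyp, i)
    m
  })
  list(mice = mice, truth = synthetic_truth(spec))
}

#' Hourly stage-conditioned spectra for a whole cohort, one mouse at a time
#'
#' Streams the cohort: for each mouse, generates the hypnogram and signals,
#' optionally applies the EMG wake override, reduces to the hourly
#' stage-conditioned spectral tensor, and discards the raw signals before
#' moving on. This keeps memory bounded by one recording regardless of
#' cohort size.
#'
#' @param spec a [cohort_spec()].
#' @param apply_override apply the Otsu EMG wake override to the generated
#'   hypnogram before conditioning (default `FALSE`: the generated labels
#'   are already ground truth).
#' @return list of per-mouse lists with `hourly` (an `hourly_stage_spectra`),
#'   `hypnogram`, and `amounts` (hourly stage minutes).
#' @export
cohort_hourly_spectra <- function(spec, apply_override = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_mice) - 1L, function(i) {
    hyp <- generate_hypnogram(spec, i)
    rec <- generate_epoch_signals(spec, hyp, i)
    if (apply_override) {
      amps <- emg_amplitude(rec)
      hyp <- apply_wake_override(hyp, amps, otsu_threshold(amps))
    }
    spectra <- epoch_spectra(rec$eeg, rec$fs)
    list(
      mouse = i,
      hourly = hourly_stage_spectra(spectra, hyp),
      hypnogram = hyp,
      amounts = hourly_stage_amounts(hyp)
    )
  })
}
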