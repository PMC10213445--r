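#' Frequency grid of the spectral analysis
#'
#' The analysis operates on a fixed 0--16 Hz grid with 0.1 Hz resolution
#' (161 bins, both endpoints included), the native resolution of a 10-s
#' epoch sampled at 128 Hz.
#'
#' @return numeric vector of 161 frequencies in Hz.
#' @export
spectral_freqs <- function() seq(0, 16, by = 0.1)

#' Default hourly stage-occupancy profiles
#'
#' Baseline probability of each vigilance stage per ZT hour for a nocturnal
#' mouse: wakefulness dominant in the dark phase (ZT12--24), NREM dominant in
#' the light phase, REM peaking late in the light phase. Each hourly triple
#' sums to 1.
#'
#' @return 24 x 3 matrix (rows ZT hours 0--23, columns WAKE/NREM/REM).
#' @export
default_stage_profile <- function() {
  zt <- 0:23 + 0.5
  wake <- 0.55 + 0.20 * cos(2 * pi * (zt - 18) / 24)
  rem  <- 0.07 - 0.03 * cos(2 * pi * (zt - 18) / 24)
  nrem <- 1 - wake - rem
  out <- cbind(WAKE = wake, NREM = nrem, REM = rem)
  rownames(out) <- 0:23
  out
}

#' Default per-stage EEG spectral templates
#'
#' Mean one-sided power versus frequency for each stage on the 0--16 Hz grid:
#' a 1/f background plus a stage-specific band (delta bump in NREM, theta
#' peaks in REM and wakefulness). Units are arbitrary; every relative
#' quantity downstream is scale free.
#'
#' @return 161 x 3 matrix (rows frequencies, columns WAKE/NREM/REM).
#' @export
default_spectral_template <- function() {
  f <- spectral_freqs()
  wake <- 8 / (1 + f) + 10 * exp(-0.5 * ((f - 8) / 1.5)^2)
  nrem <- 10 / (1 + f) + 30 * exp(-0.5 * ((f - 2.5) / 1.5)^2)
  rem  <- 6 / (1 + f) + 20 * exp(-0.5 * ((f - 7) / 1.0)^2)
  out <- cbind(WAKE = wake, NREM = nrem, REM = rem)
  rownames(out) <- sprintf("%.1f", f)
  out
}

#' Default circadian modulation map
#'
#' Per stage and frequency, the relative amplitude `a` in `[0, 1)` and peak
#' time `p` in `[0, 24)` h of the multiplicative cosine
#' `1 + a * cos(2*pi*(t - p)/24)` applied to the spectral template at ZT `t`.
#' The young-animal default modulates the NREM delta band most strongly
#' (a = 0.3, peak ZT18 at 4.0 Hz) with the peak time drifting slowly across
#' frequency, plus weaker theta-band modulation in REM and wakefulness at
#' other phases; the drift makes the hourly spectral shape an injective
#' function of time of day, so phase is decodable in principle.
#'
#' @return list with 161 x 3 matrices `a` and `p` (rows frequencies, columns
#'   WAKE/NREM/REM).
#' @export
default_modulation_map <- function() {
  f <- spectral_freqs()
  a <- cbind(
    WAKE = 0.15 * exp(-0.5 * ((f - 8) / 3.0)^2),
    NREM = 0.30 * exp(-0.5 * ((f - 4) / 2.5)^2),
    REM  = 0.20 * exp(-0.5 * ((f - 7) / 2.5)^2)
  )
  p <- cbind(
    WAKE = wrap_time(6 + 0.5 * (f - 8)),
    NREM = wrap_time(18 + 0.75 * (f - 4)),
    REM  = wrap_time(20 + 0.5 * (f - 7))
  )
  rownames(a) <- rownames(p) <- sprintf("%.1f", f)
  list(a = a, p = p)
}

#' Default EMG log-amplitude parameters
#'
#' Mean and SD of the per-epoch log10 EMG amplitude for each stage. Muscle
#' tone is high in wakefulness and low in sleep, giving the bimodal amplitude
#' distribution that the Otsu wake override exploits.
#'
#' @return 3 x 2 matrix (rows WAKE/NREM/REM, columns mean/sd), log10 units.
#' @export
default_emg_params <- function() {
  out <- rbind(WAKE = c(1.00, 0.15), NREM = c(0.30, 0.12), REM = c(0.25, 0.12))
  colnames(out) <- c("mean", "sd")
  out
}

#' Specify a synthetic cohort
#'
#' Bundles every parameter of the synthetic-data generator: cohort size and
#' recording layout, hourly stage-occupancy curves, per-stage spectral
#' templates, the per-frequency circadian modulation map, EMG amplitude
#' parameters, an aging transform, and the root seed. The defaults describe a
#' young cohort recorded for 3 days with 10-s epochs at 128 Hz.
#'
#' @param n_mice number of mice in the cohort.
#' @param days recording length in days (default 3).
#' @param epoch_s epoch length in seconds (default 10).
#' @param fs sampling rate in Hz (default 128).
#' @param lighting `"LD"` or `"DD"`. Metadata only: the generator's rhythms
#'   are clock driven by construction, so constant darkness produces the same
#'   statistical structure with hours still labelled as projected ZT.
#' @param stage_profile 24 x 3 matrix of hourly stage probabilities
#'   (WAKE/NREM/REM), each row summing to 1.
#' @param spectral_template 161 x 3 matrix of per-stage mean power on the
#'   0--16 Hz, 0.1 Hz grid; strictly positive.
#' @param modulation_map list of 161 x 3 matrices `a` (relative amplitude,
#'   in `[0, 1)`) and `p` (peak ZT hour).
#' @param emg_params 3 x 2 matrix of per-stage log10-amplitude mean and sd.
#' @param aging length-2 numeric: amplitude attenuation factor in `(0, 1]`
#'   and phase delay in hours, applied to both the modulation map and the
#'   rhythmic part of the stage profile.
#' @param zt0_offset ZT of the first epoch (default 0, lights-on start).
#' @param seed integer root seed; identical spec + seed gives bit-identical
#'   cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice,
                        days = 3,
                        epoch_s = 10,
                        fs = 128,
                        lighting = c("LD", "DD"),
                        stage_profile = default_stage_profile(),
                        spectral_template = default_spectral_template(),
                        modulation_map = default_modulation_map(),
                        emg_params = default_emg_params(),
                        aging = c(attenuation = 1, delay = 0),
                        zt0_offset = 0,
                        seed = 1L) {
  lighting <- match.arg(lighting)
  spec <- structure(
    list(
      n_mice = as.integer(n_mice), days = as.integer(days),
      epoch_s = epoch_s, fs = fs, lighting = lighting,
      stage_profile = stage_profile,
      spectral_template = spectral_template,
      modulation_map = modulation_map,
      emg_params = emg_params,
      aging = c(attenuation = unname(aging[1]), delay = unname(aging[2])),
      zt0_offset = zt0_offset,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  spec <- validate_cohort_spec(spec)
  att <- spec$aging["attenuation"]; del <- spec$aging["delay"]
  if (att != 1 || del != 0) {
    spec$aging <- c(attenuation = 1, delay = 0)
    spec <- apply_aging(spec, att, del)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d mice, %d day(s), %gs epochs @ %g Hz, %s, aging (%.2f, %+.1f h), seed %d\n",
    x$n_mice, x$days, x$epoch_s, x$fs, x$lighting,
    x$aging["attenuation"], x$aging["delay"], x$seed
  ))
  invisible(x)
}

validate_cohort_spec <- function(spec) {
  sp <- spec$stage_profile
  if (!is.matrix(sp) || nrow(sp) != 24L || ncol(sp) != 3L)
    stop("`stage_profile` must be a 24 x 3 matrix (ZT hour x WAKE/NREM/REM)")
  if (any(sp < 0) || any(abs(rowSums(sp) - 1) > 1e-9))
    stop("`stage_profile` rows must be probabilities summing to 1 (+/- 1e-9)")
  nf <- length(spectral_freqs())
  st <- spec$spectral_template
  if (!is.matrix(st) || nrow(st) != nf || ncol(st) != 3L)
    stop("`spectral_template` must be 161 x 3 (0-16 Hz by 0.1 Hz x stage)")
  if (any(!is.finite(st)) || any(st <= 0))
    stop("`spectral_template` must be strictly positive on all bins")
  mm <- spec$modulation_map
  if (!is.list(mm) || !all(c("a", "p") %in% names(mm)))
    stop("`modulation_map` must be a list with matrices `a` and `p`")
  if (!all(dim(mm$a) == c(nf, 3L)) || !all(dim(mm$p) == c(nf, 3L)))
    stop("`modulation_map$a` and `$p` must be 161 x 3 matrices")
  if (any(mm$a < 0) || any(mm$a >= 1))
    stop("modulation amplitudes must lie in [0, 1) so power stays positive")
  if (any(mm$p < 0) || any(mm$p >= 24))
    stop("modulation peak times must lie in [0, 24)")
  att <- spec$aging["attenuation"]
  if (!is.finite(att) || att <= 0 || att > 1)
    stop("aging attenuation factor must lie in (0, 1]")
  if (spec$n_mice < 0) stop("`n_mice` must be nonnegative")
  if ((3600 * 24 * spec$days) %% spec$epoch_s != 0)
    stop("recording length must be a whole number of epochs")
  spec
}

#' Apply an aging transform to a cohort specification
#'
#' Attenuates the amplitude of every circadian component and delays its peak:
#' the modulation map's `a` is multiplied by `attenuation` and its `p`
#' shifted by `delay` hours; the stage-occupancy profile's deviation from its
#' 24-h mean is scaled by `attenuation` and rotated by `delay` hours (the
#' hourly triples still sum to 1 because all three stages transform
#' identically). This emulates the attenuated, phase-delayed rhythms of old
#' animals relative to the young defaults.
#'
#' @param spec a [cohort_spec()].
#' @param attenuation amplitude scaling factor in `(0, 1]`.
#' @param delay phase delay in hours.
#' @return a new `cohort_spec`.
#' @export
apply_aging <- function(spec, attenuation, delay) {
  stopifnot(inherits(spec, "cohort_spec"))
  mm <- spec$modulation_map
  mm$a <- mm$a * attenuation
  mm$p <- wrap_time(mm$p + delay)
  sp <- spec$stage_profile
  means <- colMeans(sp)
  dev <- sweep(sp, 2, means)
  # rotate the deviation curves by `delay` hours with circular linear
  # interpolation, then attenuate
  h <- 0:23
  src <- (h - delay) %% 24
  lo <- floor(src) %% 24
  hi <- (lo + 1) %% 24
  wfrac <- src - floor(src)
  rot <- dev[lo + 1, , drop = FALSE] * (1 - wfrac) +
    dev[hi + 1, , drop = FALSE] * wfrac
  sp2 <- sweep(rot * attenuation, 2, means, "+")
  rownames(sp2) <- 0:23
  spec$stage_profile <- sp2
  spec$modulation_map <- mm
  spec$aging <- c(
    attenuation = unname(spec$aging["attenuation"] * attenuation),
    delay = unname(spec$aging["delay"] + delay)
  )
  validate_cohort_spec(spec)
}
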