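# Hypnogram handling, EMG amplitude, Otsu wake override, hourly stage amounts.

#' Construct a hypnogram
#'
#' A per-epoch sequence of vigilance-stage labels. Epoch `k` (0-based) covers
#' the half-open ZT interval `[zt0_offset + k*epoch_s/3600, ...)` wrapped
#' modulo 24.
#'
#' @param stages character vector of stage labels, one per epoch; `"WAKE"`,
#'   `"NREM"`, `"REM"` (single-letter codes `W`/`N`/`R` are accepted).
#' @param epoch_s epoch length in seconds (default 10).
#' @param zt0_offset ZT of epoch 0 in hours (default 0).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 10, zt0_offset = 0) {
  stages <- as.character(stages)
  short <- c(W = "WAKE", N = "NREM", R = "REM")
  idx <- stages %in% names(short)
  stages[idx] <- short[stages[idx]]
  if (!all(stages %in% STAGES))
    stop("stage labels must be WAKE/NREM/REM (or W/N/R)")
  structure(
    list(
      stages = stages, epoch_s = epoch_s,
      zt0_offset = zt0_offset, n_epochs = length(stages)
    ),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf(
    "<hypnogram> %d epochs of %gs (%.1f h), ZT0 offset %g; W/N/R = %d/%d/%d\n",
    x$n_epochs, x$epoch_s, x$n_epochs * x$epoch_s / 3600, x$zt0_offset,
    tab["WAKE"], tab["NREM"], tab["REM"]
  ))
  invisible(x)
}

#' ZT of each epoch of a hypnogram
#'
#' @param hyp a [hypnogram()].
#' @return numeric vector of epoch-start ZT hours in `[0, 24)`.
#' @export
epoch_zt <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  wrap_time(hyp$zt0_offset + (seq_len(hyp$n_epochs) - 1) * hyp$epoch_s / 3600)
}

#' Read / write hypnogram CSV
#'
#' The interchange format has columns `epoch_index` (0-based), `zt_hours`,
#' and `stage` (single-letter `W`/`N`/`R`).
#'
#' @param path file path.
#' @param epoch_s epoch length in seconds (default 10).
#' @return for the reader, a [hypnogram()]; the writer returns `path`
#'   invisibly.
#' @export
read_hypnogram_csv <- function(path, epoch_s = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_hours", "stage")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$epoch_index), ]
  if (!identical(as.integer(df$epoch_index), seq_len(nrow(df)) - 1L))
    stop("epoch_index must be 0-based and contiguous")
  hypnogram(df$stage, epoch_s = epoch_s, zt0_offset = df$zt_hours[1])
}

#' @rdname read_hypnogram_csv
#' @param hyp a [hypnogram()] to write.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(
    epoch_index = seq_len(hyp$n_epochs) - 1L,
    zt_hours = epoch_zt(hyp),
    stage = substr(hyp$stages, 1, 1)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-epoch EMG amplitude
#'
#' The EMG amplitude of an epoch is the log10 of the standard deviation of
#' its EMG samples (population convention, divide by n). Epochs with zero
#' sample variance have no defined log-amplitude and are flagged missing
#' (`NA`) rather than `-Inf`.
#'
#' @param rec an `epoched_recording`, or an EMG sample matrix
#'   (samples x epochs).
#' @return numeric vector of per-epoch log10 amplitudes, `NA` where the
#'   epoch has zero variance; the number of flagged epochs is attached as
#'   attribute `n_missing`.
#' @export
emg_amplitude <- function(rec) {
  emg <- if (inherits(rec, "epoched_recording")) rec$emg else as.matrix(rec)
  if (nrow(emg) < 2) stop("epochs must contain at least 2 samples")
  mu <- colMeans(emg)
  v <- colMeans(emg^2) - mu^2
  v[v < 0] <- 0
  out <- ifelse(v > 0, log10(sqrt(v)), NA_real_)
  n_missing <- sum(is.na(out))
  if (n_missing > 0)
    message(n_missing, " zero-variance epoch(s) flagged missing in EMG amplitude")
  structure(out, n_missing = n_missing)
}

#' Otsu threshold of an amplitude series
#'
#' Histogram-based threshold maximizing the between-class variance, the
#' binarization used to separate the bimodal EMG amplitude distribution
#' (low muscle tone in sleep, high in wakefulness). The histogram uses 256
#' equal-width bins spanning the observed range; the threshold is reported
#' as the upper edge of the chosen bin, and ties take the lowest boundary.
#'
#' @param values numeric amplitudes; `NA`s are ignored.
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, in the units of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  x <- values[!is.na(values)]
  if (length(unique(x)) < 2L)
    stop("Otsu threshold undefined: fewer than 2 distinct values")
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / n_bins
  bin <- pmin(pmax(floor((x - lo) / width) + 1, 1), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(counts)[-n_bins]
  w1 <- length(x) - w0
  s0 <- cumsum(counts * centers)[-n_bins]
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * centers) - s0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  # bcv is flat across empty histogram regions, so ties span the whole gap
  # between modes: take the mean of the maximizing boundaries, which puts
  # the threshold mid-gap for well-separated bimodal data
  j <- mean(which(bcv >= max(bcv) * (1 - 1e-10)))
  lo + j * width
}

#' EMG-based wake override
#'
#' Epochs whose EMG amplitude strictly exceeds the threshold are relabelled
#' WAKE regardless of their scored stage; all other epochs, including those
#' with missing amplitude, keep their label. The override never converts a
#' label to NREM or REM and is idempotent.
#'
#' @param hyp a [hypnogram()].
#' @param amps per-epoch amplitudes from [emg_amplitude()].
#' @param threshold the Otsu (or other) threshold.
#' @return a new [hypnogram()].
#' @export
apply_wake_override <- function(hyp, amps, threshold) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(amps) != hyp$n_epochs)
    stop("amplitude series and hypnogram lengths differ")
  stages <- hyp$stages
  stages[!is.na(amps) & amps > threshold] <- "WAKE"
  hypnogram(stages, epoch_s = hyp$epoch_s, zt0_offset = hyp$zt0_offset)
}

#' Hourly stage amounts
#'
#' Minutes of each stage per recording hour, the series used for cosinor
#' fitting of sleep--wake rhythms.
#'
#' @param hyp a [hypnogram()] covering a whole number of hours.
#' @return tibble with columns `hour` (0-based recording hour), `zt`
#'   (ZT of the hour start), and per-stage minutes `WAKE`, `NREM`, `REM`.
#' @export
hourly_stage_amounts <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  per_hour <- 3600 / hyp$epoch_s
  if (hyp$n_epochs %% per_hour != 0)
    stop("recording must cover a whole number of hours; trim upstream")
  n_hours <- hyp$n_epochs / per_hour
  hour <- rep(seq_len(n_hours) - 1L, each = per_hour)
  counts <- table(
    factor(hour, levels = seq_len(n_hours) - 1L),
    factor(hyp$stages, levels = STAGES)
  )
  mins <- unclass(counts) * hyp$epoch_s / 60
  tibble::tibble(
    hour = seq_len(n_hours) - 1L,
    zt = wrap_time(hyp$zt0_offset + seq_len(n_hours) - 1L),
    WAKE = unname(mins[, "WAKE"]),
    NREM = unname(mins[, "NREM"]),
    REM = unname(mins[, "REM"])
  )
}
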