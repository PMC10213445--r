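# Circadian component extraction: relative normalization of hourly power,
# first Fourier harmonic (amplitude + peak time), cosinor fitting, and
# circular two-sample statistics.

#' Normalize hourly power series to relative deviations
#'
#' For each (stage, frequency) series of hourly power, subtracts and divides
#' by the series mean: `norm_i = (hourly_i - ave) / ave`, with the mean
#' taken over non-missing hours. The result is the dimensionless relative
#' deviation of EEG power from its time average; its non-missing mean is 0
#' by construction. Missing hours stay missing.
#'
#' @param hss an `hourly_stage_spectra`.
#' @param min_hours minimum number of non-missing hours a series needs
#'   (default 24, one full cycle).
#' @param strict if `TRUE`, a series failing the prerequisites (too few
#'   hours, or nonpositive average power) is an error; the default drops it
#'   to all-missing with a warning.
#' @return object of class `normalized_power`: list with `norm` (array hour
#'   x stage x frequency), `ave` (stage x frequency mean power), `freqs`,
#'   `n_hours_used` (stage x frequency).
#' @export
normalize_power <- function(hss, min_hours = 24L, strict = FALSE) {
  stopifnot(inherits(hss, "hourly_stage_spectra"))
  dims <- dim(hss$power)
  norm <- array(NA_real_, dims, dimnames = dimnames(hss$power))
  ave <- matrix(NA_real_, dims[2], dims[3],
                dimnames = dimnames(hss$power)[2:3])
  used <- matrix(0L, dims[2], dims[3], dimnames = dimnames(ave))
  dropped <- 0L
  for (s in seq_len(dims[2])) {
    cell <- array(hss$power[, s, ], c(dims[1], dims[3]))  # hours x freqs
    ok_hours <- !is.na(cell[, 1])
    n_ok <- sum(ok_hours)
    if (n_ok < min_hours) {
      msg <- sprintf("stage %s has only %d non-missing hour(s)", STAGES[s], n_ok)
      if (strict) stop(msg)
      dropped <- dropped + dims[3]
      next
    }
    mu <- colMeans(cell[ok_hours, , drop = FALSE])
    bad <- !(mu > 0)
    if (any(bad)) {
      if (strict) stop("nonpositive average power in stage ", STAGES[s])
      dropped <- dropped + sum(bad)
    }
    good <- which(!bad)
    norm[, s, good] <- sweep(sweep(cell[, good, drop = FALSE], 2, mu[good]),
                             2, mu[good], "/")
    ave[s, good] <- mu[good]
    used[s, good] <- n_ok
  }
  if (dropped > 0)
    warning(dropped, " (stage, frequency) series dropped (insufficient hours or zero power)")
  structure(
    list(norm = norm, ave = ave, freqs = hss$freqs, n_hours_used = used),
    class = "normalized_power"
  )
}

#' First Fourier harmonic of an hourly series
#'
#' Computes the 24-h cosine and sine components of an hourly series:
#' `COS = (2/T') * sum_i x_i cos(2*pi*i*dt/tau)` and likewise with sine,
#' with period `tau = 24` h and interval `dt = 1` h. The index `i` is the
#' 1-based hour number, so the value of hour bin `[i-1, i)` is assigned time
#' `i*dt`; sums run over non-missing hours only, with `T'` their count.
#'
#' @param x hourly values (may contain `NA`); position `k` is hour `i = k`.
#' @param tau period in hours (default 24).
#' @param dt sampling interval in hours (default 1).
#' @param time_assign `"index"` assigns hour `i` the time `i*dt` (default);
#'   `"center"` uses the bin center `(i - 0.5)*dt` for sensitivity analysis.
#' @return named numeric `c(cos = COS, sin = SIN)`.
#' @export
fourier_component <- function(x, tau = 24, dt = 1,
                              time_assign = c("index", "center")) {
  time_assign <- match.arg(time_assign)
  i <- seq_along(x)
  t_i <- if (time_assign == "index") i * dt else (i - 0.5) * dt
  ok <- !is.na(x)
  if (!any(ok)) return(c(cos = NA_real_, sin = NA_real_))
  Tn <- sum(ok)
  ang <- 2 * pi * t_i[ok] / tau
  c(
    cos = 2 / Tn * sum(x[ok] * cos(ang)),
    sin = 2 / Tn * sum(x[ok] * sin(ang))
  )
}

#' Amplitude and peak time from first-harmonic components
#'
#' `A = sqrt(COS^2 + SIN^2)`; `t_p = arctan2(SIN, COS)/(2*pi) * 24`, wrapped
#' into `[0, 24)`. `t_p` is the clock time at which the fitted 24-h cosine
#' is maximal. When `A` is 0 the peak time is undefined and returned `NA`.
#'
#' @param cs named vector `c(cos, sin)` from [fourier_component()], or the
#'   COS value if `sin_` is given.
#' @param sin_ optional SIN value.
#' @return named numeric `c(amplitude, peak)` with peak in hours.
#' @export
amplitude_peaktime <- function(cs, sin_ = NULL) {
  if (!is.null(sin_)) cs <- c(cos = cs[[1]], sin = sin_)
  A <- sqrt(cs[["cos"]]^2 + cs[["sin"]]^2)
  tp <- if (!is.finite(A) || A == 0) NA_real_ else
    wrap_time(atan2(cs[["sin"]], cs[["cos"]]) / (2 * pi) * 24)
  c(amplitude = A, peak = tp)
}

#' Circadian components for every stage and frequency
#'
#' Runs [normalize_power()], [fourier_component()] and
#' [amplitude_peaktime()] over the whole hourly tensor.
#'
#' @param hss an `hourly_stage_spectra`.
#' @param ... passed to [normalize_power()] and [fourier_component()].
#' @return tibble with columns `stage`, `freq_hz`, `cos`, `sin`,
#'   `amplitude`, `peak_zt`, `n_hours`, `mean_power`.
#' @export
rhythm_components <- function(hss, ...) {
  dots <- list(...)
  np_args <- dots[names(dots) %in% c("min_hours", "strict")]
  fc_args <- dots[names(dots) %in% c("tau", "dt", "time_assign")]
  np <- do.call(normalize_power, c(list(hss), np_args))
  nf <- length(np$freqs)
  out <- vector("list", 3L * nf)
  k <- 0L
  for (s in seq_along(STAGES)) {
    for (f in seq_len(nf)) {
      k <- k + 1L
      series <- np$norm[, s, f]
      if (all(is.na(series))) {
        out[[k]] <- list(STAGES[s], np$freqs[f], NA_real_, NA_real_,
                         NA_real_, NA_real_, 0L, np$ave[s, f])
        next
      }
      cs <- do.call(fourier_component, c(list(series), fc_args))
      ap <- amplitude_peaktime(cs)
      out[[k]] <- list(STAGES[s], np$freqs[f], cs[["cos"]], cs[["sin"]],
                       ap[["amplitude"]], ap[["peak"]],
                       np$n_hours_used[s, f], np$ave[s, f])
    }
  }
  df <- do.call(rbind.data.frame, out)
  names(df) <- c("stage", "freq_hz", "cos", "sin", "amplitude", "peak_zt",
                 "n_hours", "mean_power")
  tibble::as_tibble(df)
}

#' Cosinor fit of an hourly series
#'
#' Least-squares fit of `y = M + A*cos(2*pi*(t - phi)/P)` over mesor `M`,
#' amplitude `A >= 0`, acrophase `phi`, and period `P` (bounded, default
#' 20--28 h), by Levenberg--Marquardt. Initialization: `M` at the series
#' mean, `A` at half the range, `phi` from the first-harmonic estimator at
#' the initial 24-h period.
#'
#' @param y hourly values.
#' @param t times in hours (default `0:(length(y)-1)`).
#' @param period_bounds lower/upper bound on the period in hours.
#' @return list with `mesor`, `amplitude`, `acrophase` (wrapped to
#'   `[0, P)`), `period`, `rss`, `converged`, and `flat` (`TRUE` when the
#'   series carries no resolvable rhythm so the period is unidentifiable).
#' @export
cosinor_fit <- function(y, t = seq_along(y) - 1, period_bounds = c(20, 28)) {
  ok <- !is.na(y) & !is.na(t)
  y <- y[ok]; t <- t[ok]
  if (length(y) < 8) stop("cosinor fit needs at least 8 points")
  M0 <- mean(y)
  A0 <- (max(y) - min(y)) / 2
  if (A0 == 0 || stats::sd(y) < 1e-12 * (abs(M0) + 1)) {
    return(list(mesor = M0, amplitude = 0, acrophase = NA_real_,
                period = NA_real_, rss = 0, converged = TRUE, flat = TRUE))
  }
  ang <- 2 * pi * t / 24
  c1 <- 2 * mean((y - M0) * cos(ang))
  s1 <- 2 * mean((y - M0) * sin(ang))
  phi0 <- wrap_time(atan2(s1, c1) / (2 * pi) * 24)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ M + A * cos(2 * pi * (t - phi) / P),
      start = list(M = M0, A = A0, phi = phi0, P = 24),
      lower = c(M = -Inf, A = 0, phi = -Inf, P = period_bounds[1]),
      upper = c(M = Inf, A = Inf, phi = Inf, P = period_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(mesor = M0, amplitude = NA_real_, acrophase = NA_real_,
                period = NA_real_, rss = NA_real_, converged = FALSE,
                flat = FALSE, message = conditionMessage(fit)))
  }
  cf <- coef(fit)
  P <- unname(cf["P"])
  list(
    mesor = unname(cf["M"]),
    amplitude = unname(cf["A"]),
    acrophase = unname(cf["phi"]) %% P,
    period = P,
    rss = sum(stats::residuals(fit)^2),
    converged = TRUE,
    flat = FALSE
  )
}

#' Mardia--Watson--Wheeler two-sample test for circular data
#'
#' Uniform-scores test of whether two samples of clock times (hours on the
#' 24-h circle) come from the same circular distribution. Pooled
#' observations receive circular ranks (midranks for ties) mapped to
#' uniformly spaced angles; the statistic is
#' `W = 2 * sum_g (C_g^2 + S_g^2) / n_g` over the groups' resultant
#' components. Two p-values are reported: the asymptotic chi-square with
#' 2 df, and a permutation p (group labels permuted, same scores).
#'
#' @param times1,times2 clock times in hours.
#' @param n_perm number of label permutations (default 9999); 0 skips the
#'   permutation p.
#' @param seed seed for the permutation draw.
#' @return list with `W`, `p_chisq`, `p_perm`, `n1`, `n2`.
#' @export
mww_test <- function(times1, times2, n_perm = 9999, seed = 1L) {
  times1 <- times1[!is.na(times1)]; times2 <- times2[!is.na(times2)]
  n1 <- length(times1); n2 <- length(times2)
  if (n1 < 4 || n2 < 4) stop("each group needs at least 4 observations")
  all_t <- wrap_time(c(times1, times2))
  N <- n1 + n2
  beta <- 2 * pi * rank(all_t, ties.method = "average") / N
  grp <- rep(1:2, c(n1, n2))
  w_stat <- function(g) {
    w <- 0
    for (gi in 1:2) {
      b <- beta[g == gi]
      w <- w + (sum(cos(b))^2 + sum(sin(b))^2) / length(b)
    }
    2 * w
  }
  W <- w_stat(grp)
  p_chisq <- stats::pchisq(W, df = 2, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (w_stat(sample(grp)) >= W - 1e-12) exceed <- exceed + 1L
    }
    p_perm <- (1 + exceed) / (n_perm + 1)
  }
  list(W = W, p_chisq = p_chisq, p_perm = p_perm, n1 = n1, n2 = n2)
}
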