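# Estimation of subjective circadian time from hourly normalized EEG
# spectral distributions: circular target encoding, a bank of regressors
# fit separately to the cosine and sine components, leave-one-out
# evaluation with the cosine accuracy statistic, and random-forest feature
# importance.

PHASE_ALGORITHMS <- c("linear", "ridge", "knn", "svm", "random_forest")
PHASE_MODES <- c("nrem", "rem", "wake", "pooled", "all_stages")

#' Encode clock time on the unit circle
#'
#' Maps a time of day to `{cos(ZT/24*2*pi), sin(ZT/24*2*pi)}`, the
#' two-component regression target. Periodic in 24 h.
#'
#' @param zt times in hours.
#' @return matrix with columns `x` and `y`; rows on the unit circle.
#' @export
encode_time <- function(zt) {
  ang <- zt / 24 * 2 * pi
  cbind(x = cos(ang), y = sin(ang))
}

#' Decode clock time from a plane point
#'
#' `arctan2(y, x)/(2*pi) * 24`, wrapped into `[0, 24)`. The point need not
#' lie on the unit circle (regressor outputs are unconstrained); only the
#' angle matters. The zero vector has no angle and decodes to `NA`.
#'
#' @param x,y plane coordinates (vectors).
#' @return times in hours.
#' @export
decode_time <- function(x, y) {
  out <- wrap_time(atan2(y, x) / (2 * pi) * 24)
  out[x == 0 & y == 0] <- NA_real_
  out
}

#' Accuracy of estimated circadian times
#'
#' Mean over samples of `cos{(estimated - ZT)/24 * 2*pi}`: 1 for perfect
#' estimation, -1 when every estimate is in antiphase (12 h off), 0 for a
#' constant 6-h error. Invariant to adding multiples of 24 h to either
#' argument.
#'
#' @param estimated,zt times in hours, equal length.
#' @param na.rm drop pairs with missing estimates (default `TRUE`).
#' @return accuracy in `[-1, 1]`.
#' @export
phase_accuracy <- function(estimated, zt, na.rm = TRUE) {
  d <- (estimated - zt) / 24 * 2 * pi
  mean(cos(d), na.rm = na.rm)
}

#' Hourly phase-estimation features for one mouse
#'
#' Builds the per-hour feature vectors from an hourly stage-conditioned
#' spectral tensor, in one of five input modes: a single stage's normalized
#' spectrum (`"nrem"`, `"rem"`, `"wake"`), the pooled hourly spectrum
#' ignoring stages (`"pooled"`), or the concatenation of all three stage
#' spectra (`"all_stages"`). Each constituent spectrum is unit-sum
#' normalized; the 0 Hz bin is excluded (identically ~0 after epoch mean
#' removal). Hours in which a single-stage mode's stage is absent are
#' dropped; in `all_stages` mode a missing constituent is imputed with the
#' mouse's time-averaged normalized spectrum for that stage and flagged.
#'
#' @param hss an `hourly_stage_spectra` for one mouse.
#' @param mode one of `"nrem"`, `"rem"`, `"wake"`, `"pooled"`,
#'   `"all_stages"`.
#' @return object of class `phase_features`: list with `features` (hours x
#'   p matrix), `zt` (hour-start ZT per row), `hour` (0-based recording
#'   hour), `imputed` (logical per row), `mode`, `freqs`.
#' @export
phase_features <- function(hss, mode = c("all_stages", "nrem", "rem", "wake", "pooled")) {
  stopifnot(inherits(hss, "hourly_stage_spectra"))
  mode <- match.arg(mode)
  keep_f <- hss$freqs > 0
  freqs <- hss$freqs[keep_f]
  n_hours <- dim(hss$power)[1]
  unit_rows <- function(m) m / rowSums(m)
  if (mode %in% c("nrem", "rem", "wake")) {
    stage <- c(nrem = "NREM", rem = "REM", wake = "WAKE")[[mode]]
    cell <- hss$power[, stage, keep_f]
    ok <- hss$n_epochs[, stage] > 0
    feats <- unit_rows(cell[ok, , drop = FALSE])
    colnames(feats) <- paste0(stage, "_", sprintf("%.1f", freqs))
    hour <- which(ok) - 1L
    imputed <- rep(FALSE, sum(ok))
  } else if (mode == "pooled") {
    pooled <- pool_stages(hss)[, keep_f, drop = FALSE]
    ok <- rowSums(hss$n_epochs) > 0
    feats <- unit_rows(pooled[ok, , drop = FALSE])
    colnames(feats) <- paste0("ALL_", sprintf("%.1f", freqs))
    hour <- which(ok) - 1L
    imputed <- rep(FALSE, sum(ok))
  } else {
    blocks <- list()
    present <- matrix(FALSE, n_hours, 3L)
    for (s in seq_along(STAGES)) {
      cell <- hss$power[, STAGES[s], keep_f]
      ok <- hss$n_epochs[, STAGES[s]] > 0
      present[, s] <- ok
      norm <- matrix(NA_real_, n_hours, sum(keep_f))
      norm[ok, ] <- unit_rows(cell[ok, , drop = FALSE])
      if (!any(ok)) stop("stage ", STAGES[s], " never occurs; cannot impute")
      if (any(!ok)) {
        fallback <- colMeans(norm[ok, , drop = FALSE])
        norm[!ok, ] <- matrix(fallback, sum(!ok), length(fallback), byrow = TRUE)
      }
      colnames(norm) <- paste0(STAGES[s], "_", sprintf("%.1f", freqs))
      blocks[[s]] <- norm
    }
    feats <- do.call(cbind, blocks)
    hour <- seq_len(n_hours) - 1L
    imputed <- !apply(present, 1, all)
  }
  # quantize away sub-precision rounding residue: averaging different epoch
  # counts leaves count-dependent noise at ~1e-16 relative, which scale-free
  # learners would otherwise treat as a real covariate in degenerate
  # (rhythm-free) data; 12 significant digits is far below any signal
  feats <- signif(feats, 12)
  structure(
    list(
      features = feats, zt = hss$zt[hour + 1L], hour = hour,
      imputed = imputed, mode = mode, freqs = freqs
    ),
    class = "phase_features"
  )
}

# stack per-mouse phase_features into one design matrix + targets
bind_features <- function(feature_list) {
  stopifnot(length(feature_list) > 0)
  modes <- vapply(feature_list, function(f) f$mode, "")
  if (length(unique(modes)) != 1L) stop("input modes differ across mice")
  X <- do.call(rbind, lapply(feature_list, function(f) f$features))
  zt <- unlist(lapply(feature_list, function(f) f$zt))
  mouse <- rep(seq_along(feature_list) - 1L,
               vapply(feature_list, function(f) length(f$zt), 1L))
  list(X = X, zt = zt, mouse = mouse, mode = modes[1])
}

fit_single_regressor <- function(X, y, algorithm, seed) {
  df <- as.data.frame(X)
  switch(
    algorithm,
    linear = {
      fit <- stats::lm(y ~ ., data = cbind(y = y, df))
      cf <- coef(fit); cf[is.na(cf)] <- 0
      list(kind = "linear", intercept = cf[1], beta = cf[-1])
    },
    ridge = {
      fit <- MASS::lm.ridge(y ~ ., data = cbind(y = y, df), lambda = 1)
      cf <- coef(fit)
      list(kind = "linear", intercept = cf[1], beta = cf[-1])
    },
    knn = {
      list(kind = "knn", fit = caret::knnreg(df, y, k = 5))
    },
    svm = {
      list(kind = "svm", fit = e1071::svm(x = df, y = y))
    },
    random_forest = {
      list(kind = "ranger",
           fit = ranger::ranger(
             y = y, x = df, num.trees = 500, importance = "impurity",
             seed = seed, num.threads = 1
           ))
    },
    stop("unknown algorithm: ", algorithm)
  )
}

predict_single <- function(reg, X) {
  df <- as.data.frame(X)
  switch(
    reg$kind,
    linear = as.numeric(reg$intercept + as.matrix(df) %*% reg$beta),
    knn = as.numeric(predict(reg$fit, df)),
    svm = as.numeric(predict(reg$fit, df)),
    ranger = as.numeric(predict(reg$fit, data = df, num.threads = 1)$predictions)
  )
}

#' Fit a circadian phase-estimation model
#'
#' Trains two independent single-output regressors, one for the cosine (x)
#' and one for the sine (y) component of the encoded time, using the chosen
#' algorithm with its implementation defaults: `lm` (linear),
#' `MASS::lm.ridge` with lambda 1 (ridge), `caret::knnreg` with k = 5
#' (knn), `e1071::svm` eps-regression with a radial kernel (svm), or
#' `ranger` with 500 trees and impurity importance (random_forest).
#'
#' @param features a `phase_features` object or list of them (one per
#'   training mouse).
#' @param algorithm one of `r paste(PHASE_ALGORITHMS, collapse = ", ")`.
#' @param seed integer seed controlling any algorithmic randomness.
#' @return object of class `phase_model`.
#' @export
fit_phase_model <- function(features, algorithm = PHASE_ALGORITHMS, seed = 0L) {
  algorithm <- match.arg(algorithm)
  if (inherits(features, "phase_features")) features <- list(features)
  tr <- bind_features(features)
  if (nrow(tr$X) < 2) stop("need at least 2 training samples")
  tgt <- encode_time(tr$zt)
  set.seed(seed)
  mx <- fit_single_regressor(tr$X, tgt[, "x"], algorithm, seed = seed)
  my <- fit_single_regressor(tr$X, tgt[, "y"], algorithm, seed = seed + 100003L)
  structure(
    list(x_model = mx, y_model = my, algorithm = algorithm,
         mode = tr$mode, p = ncol(tr$X), feature_names = colnames(tr$X),
         seed = seed),
    class = "phase_model"
  )
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase_model> %s, mode %s, %d features\n",
              x$algorithm, x$mode, x$p))
  invisible(x)
}

#' Predict subjective circadian time
#'
#' @param object a [fit_phase_model()] result.
#' @param features a `phase_features` object (same mode and
#'   dimensionality as the training features).
#' @param ... unused.
#' @return tibble with `hour`, `zt`, `x`, `y`, `estimated` (hours).
#' @export
predict.phase_model <- function(object, features, ...) {
  stopifnot(inherits(features, "phase_features"))
  if (features$mode != object$mode)
    stop("feature mode ", features$mode, " does not match model mode ", object$mode)
  if (ncol(features$features) != object$p)
    stop("feature dimensionality mismatch")
  xh <- predict_single(object$x_model, features$features)
  yh <- predict_single(object$y_model, features$features)
  tibble::tibble(
    hour = features$hour, zt = features$zt,
    x = xh, y = yh, estimated = decode_time(xh, yh)
  )
}

#' Leave-one-out evaluation of a phase-estimation model
#'
#' For each mouse, trains on all other mice and predicts the held-out
#' mouse's hourly times; the accuracy is the mean of
#' `cos{(estimated - ZT)/24*2*pi}` over all held-out samples. Stochastic
#' algorithms are repeated `n_trials` times with seeds `0 .. n_trials-1`
#' and averaged; deterministic algorithms run once.
#'
#' @param feature_list list of `phase_features`, one per mouse (>= 3).
#' @param algorithm regression algorithm (see [fit_phase_model()]).
#' @param n_trials trials for stochastic algorithms (default 5).
#' @return list with `accuracy` (mean over trials), `per_trial`,
#'   `per_mouse` (trials x mice accuracy matrix), `predictions` (tibble of
#'   the last trial's held-out predictions), `algorithm`, `mode`.
#' @export
loo_evaluate <- function(feature_list, algorithm = PHASE_ALGORITHMS, n_trials = 5L) {
  algorithm <- match.arg(algorithm)
  n_mice <- length(feature_list)
  if (n_mice < 3) stop("leave-one-out evaluation needs at least 3 mice")
  if (algorithm %in% c("linear", "ridge", "knn", "svm")) n_trials <- 1L
  per_mouse <- matrix(NA_real_, n_trials, n_mice)
  per_trial <- numeric(n_trials)
  preds <- NULL
  for (trial in seq_len(n_trials)) {
    seed <- trial - 1L
    rows <- vector("list", n_mice)
    for (m in seq_len(n_mice)) {
      model <- fit_phase_model(feature_list[-m], algorithm, seed = seed)
      pr <- predict(model, feature_list[[m]])
      pr$mouse <- m - 1L
      rows[[m]] <- pr
      per_mouse[trial, m] <- phase_accuracy(pr$estimated, pr$zt)
    }
    preds <- do.call(rbind, rows)
    per_trial[trial] <- phase_accuracy(preds$estimated, preds$zt)
  }
  list(
    accuracy = mean(per_trial), per_trial = per_trial,
    per_mouse = per_mouse, predictions = tibble::as_tibble(preds),
    algorithm = algorithm, mode = feature_list[[1]]$mode,
    n_trials = n_trials
  )
}

#' Predict one cohort's circadian times with a model trained on another
#'
#' Applies a trained phase model to every mouse of a test cohort and
#' summarizes, per time point, the circular mean estimated time and the
#' circular mean phase delay `ZT - estimated` (positive values mean the
#' estimated subjective time lags the environmental time).
#'
#' @param model a [fit_phase_model()] result (e.g. trained on young LD mice).
#' @param feature_list list of `phase_features` for the test cohort.
#' @return list with `predictions` (tibble: mouse, hour, zt, estimated) and
#'   `by_zt` (tibble: zt, mean_estimated, delay_h, n).
#' @export
cross_cohort_predict <- function(model, feature_list) {
  stopifnot(inherits(model, "phase_model"))
  if (inherits(feature_list, "phase_features")) feature_list <- list(feature_list)
  rows <- lapply(seq_along(feature_list), function(m) {
    pr <- predict(model, feature_list[[m]])
    pr$mouse <- m - 1L
    pr
  })
  preds <- do.call(rbind, rows)
  zts <- sort(unique(preds$zt))
  by_zt <- tibble::tibble(
    zt = zts,
    mean_estimated = vapply(zts, function(z)
      circular_mean(preds$estimated[preds$zt == z]), 1.0),
    delay_h = vapply(zts, function(z) {
      est <- preds$estimated[preds$zt == z]
      m <- circular_mean(est)
      if (is.na(m)) NA_real_ else circ_diff(z, m)
    }, 1.0),
    n = vapply(zts, function(z) sum(preds$zt == z), 1L)
  )
  list(predictions = tibble::as_tibble(preds), by_zt = by_zt)
}

#' Random-forest feature importance of a phase model
#'
#' Impurity-based importances per input frequency bin, reported separately
#' for the cosine (x) and sine (y) regressors and normalized to sum to 1
#' per regressor; also aggregated per stage. The cosine component
#' discriminates morning from evening, the sine component day from night.
#'
#' @param model a random-forest [fit_phase_model()] result.
#' @return list with `per_feature` (tibble: feature, stage, freq_hz,
#'   importance_x, importance_y) and `per_stage` (tibble: stage,
#'   importance_x, importance_y).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "phase_model"))
  if (model$algorithm != "random_forest")
    stop("feature importance requires a random_forest model")
  ix <- ranger::importance(model$x_model$fit)
  iy <- ranger::importance(model$y_model$fit)
  ix <- ix / sum(ix); iy <- iy / sum(iy)
  nm <- model$feature_names
  stage <- sub("_.*$", "", nm)
  freq <- as.numeric(sub("^[A-Z]+_", "", nm))
  per_feature <- tibble::tibble(
    feature = nm, stage = stage, freq_hz = freq,
    importance_x = as.numeric(ix[nm]), importance_y = as.numeric(iy[nm])
  )
  agg <- function(v) vapply(split(v, stage), sum, 1.0)
  st <- sort(unique(stage))
  per_stage <- tibble::tibble(
    stage = st,
    importance_x = agg(per_feature$importance_x)[st],
    importance_y = agg(per_feature$importance_y)[st]
  )
  list(per_feature = per_feature, per_stage = per_stage)
}
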