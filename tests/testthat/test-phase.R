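# Circular time encoding/decoding, the regressor bank, LOO evaluation,
# cross-cohort prediction, and feature importance.

test_that("time encoding and decoding are mutually inverse", {
  expect_equal(unname(encode_time(0)), matrix(c(1, 0), 1), tolerance = 1e-12)
  expect_equal(unname(encode_time(6)), matrix(c(0, 1), 1), tolerance = 1e-12)
  expect_equal(unname(encode_time(18)), matrix(c(0, -1), 1), tolerance = 1e-12)
  expect_equal(decode_time(1, 0), 0)
  expect_equal(decode_time(0, -1), 18)
  expect_equal(decode_time(-0.2, -0.2), 15)
  expect_true(is.na(decode_time(0, 0)))
  for (t in seq(0, 23.9, by = 0.37)) {
    e <- encode_time(t)
    expect_lt(abs(circ_diff(decode_time(e[, "x"], e[, "y"]), t)), 1e-9)
  }
})

test_that("the accuracy statistic hits its analytic anchors", {
  zt <- 0:23
  expect_equal(phase_accuracy(zt, zt), 1)
  expect_equal(phase_accuracy(wrap_time(zt + 12), zt), -1)
  expect_equal(phase_accuracy(wrap_time(zt + 6), zt), 0, tolerance = 1e-12)
  expect_equal(phase_accuracy(zt + 24, zt), 1)  # 24-h periodicity
  withr::with_seed(17, {
    est <- runif(50, 0, 24); zt2 <- runif(50, 0, 24)
  })
  acc <- phase_accuracy(est, zt2)
  expect_gte(acc, -1); expect_lte(acc, 1)
})

test_that("linear regression inverts a linear feature map exactly", {
  zt <- rep(0:23, 3)
  tgt <- encode_time(zt)
  A <- matrix(c(2, -1, 0.5, 3, 1, 1, -2, 0.25), 2)  # full-rank 2 -> 4 map
  X <- tgt %*% A
  feats <- make_phase_features(X, zt)
  model <- fit_phase_model(feats, "linear", seed = 0)
  pred <- predict(model, feats)
  expect_gt(phase_accuracy(pred$estimated, zt), 0.999)
})

test_that("every algorithm trains, predicts, and is seed-deterministic", {
  feats <- analytic_mouse_features(hours = 72, noise_sd = 0.05, seed = 18)
  for (alg in c("linear", "ridge", "knn", "svm", "random_forest")) {
    m1 <- fit_phase_model(feats, alg, seed = 7)
    p1 <- predict(m1, feats)
    expect_false(any(is.na(p1$estimated)))
    m2 <- fit_phase_model(feats, alg, seed = 7)
    p2 <- predict(m2, feats)
    expect_identical(p1$estimated, p2$estimated)
    # training-set accuracy should be clearly positive on a clean mapping
    expect_gt(phase_accuracy(p1$estimated, p1$zt), 0.5)
  }
  expect_error(fit_phase_model(feats, "boosting"), "arg")
})

test_that("knn LOO on a noiseless injective mapping is nearly perfect", {
  cohort <- lapply(1:4, function(i)
    analytic_mouse_features(hours = 72, noise_sd = 0.01, seed = 100 + i))
  res <- loo_evaluate(cohort, "knn")
  expect_gte(res$accuracy, 0.95)
  expect_identical(res$n_trials, 1L)
})

test_that("LOO accuracy degrades gracefully with phase-uninformative input", {
  # features independent of time: accuracy should be near zero
  cohort <- lapply(1:3, function(i) {
    X <- withr::with_seed(200 + i, matrix(rnorm(72 * 6), 72))
    make_phase_features(X, (seq_len(72) - 1) %% 24)
  })
  res <- loo_evaluate(cohort, "knn")
  expect_lt(abs(res$accuracy), 0.35)
})

test_that("cross-cohort prediction reports the injected phase shift", {
  young <- lapply(1:4, function(i)
    analytic_mouse_features(hours = 72, noise_sd = 0.02, seed = 300 + i))
  shifted <- lapply(1:3, function(i)
    analytic_mouse_features(hours = 72, noise_sd = 0.02, seed = 400 + i,
                            phase_shift = 2))
  model <- fit_phase_model(young, "knn", seed = 0)
  cc <- cross_cohort_predict(model, shifted)
  # the shifted cohort's state at ZT t matches the reference at t - 2,
  # so the estimate lags by ~2 h at every time point
  delays <- cc$by_zt$delay_h
  expect_true(all(abs(delays - 2) < 0.8))
  # train-on-self sanity: delay ~ 0
  cc0 <- cross_cohort_predict(model, young)
  expect_lt(max(abs(cc0$by_zt$delay_h)), 0.5)
})

test_that("mode mismatches and bad feature dimensions are caught", {
  feats <- analytic_mouse_features(hours = 48, seed = 19)
  model <- fit_phase_model(feats, "knn")
  other <- feats; other$mode <- "nrem"
  class(other) <- "phase_features"
  expect_error(predict(model, other), "mode")
  wide <- make_phase_features(cbind(feats$features, extra = 1), feats$zt)
  expect_error(predict(model, wide), "dimensionality")
})

test_that("random-forest importances normalize and localize the signal", {
  # only the first two features carry time information
  zt <- rep(0:23, 3)
  tgt <- encode_time(zt)
  withr::with_seed(20, {
    X <- cbind(tgt, matrix(rnorm(72 * 6, 0, 1), 72))
  })
  colnames(X) <- paste0("NREM_", seq_len(ncol(X)))
  feats <- make_phase_features(X, zt)
  model <- fit_phase_model(feats, "random_forest", seed = 1)
  imp <- feature_importance(model)
  expect_equal(sum(imp$per_feature$importance_x), 1, tolerance = 1e-9)
  expect_equal(sum(imp$per_feature$importance_y), 1, tolerance = 1e-9)
  ord_x <- order(imp$per_feature$importance_x, decreasing = TRUE)
  expect_lte(min(which(ord_x %in% 1:2)), 2)  # informative feature ranks top
  expect_error(feature_importance(fit_phase_model(feats, "knn")), "random_forest")
})

test_that("all-stages features impute missing stage-hours and flag them", {
  power <- array(rexp(6 * 3 * 4, 0.5) + 1, c(6, 3, 4),
                 dimnames = list(NULL, STAGES, c("0.0", "0.1", "0.2", "0.3")))
  n_ep <- matrix(5L, 6, 3, dimnames = list(NULL, STAGES))
  n_ep[3, "REM"] <- 0L
  power[3, "REM", ] <- NA
  hss <- structure(
    list(power = power, n_epochs = n_ep, freqs = c(0, 0.1, 0.2, 0.3),
         zt = 0:5, epoch_s = 10),
    class = "hourly_stage_spectra"
  )
  f_all <- phase_features(hss, "all_stages")
  expect_identical(nrow(f_all$features), 6L)
  expect_identical(f_all$imputed, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(any(is.na(f_all$features)))
  # the DC bin is excluded and each constituent block sums to 1
  expect_identical(ncol(f_all$features), 9L)
  rem_block <- f_all$features[, grep("^REM", colnames(f_all$features))]
  # unit sums up to the 12-significant-digit feature quantization
  expect_equal(unname(rowSums(rem_block)), rep(1, 6), tolerance = 1e-9)
  # single-stage mode drops the missing hour instead
  f_rem <- phase_features(hss, "rem")
  expect_identical(nrow(f_rem$features), 5L)
  expect_false(3L %in% (f_rem$hour + 1L))
  # pooled mode keeps every hour and weights by epoch counts
  f_pool <- phase_features(hss, "pooled")
  expect_identical(nrow(f_pool$features), 6L)
})
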