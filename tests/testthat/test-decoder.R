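test_that("calibration separates a strongly lateralized user", {
  ep <- synthetic_mi_epochs(30, 30, erd_depth = 0.8, noise_sd = 1, seed = 31)
  dec <- calibrate_decoder(ep, seed = 31)
  expect_gt(dec$cv_accuracy, 0.9)

  # logistic-regression oracle on the same feature pipeline
  fl <- pamgame:::bandpass_mu_beta(ep$samples, ep$rate)
  epf <- ep; epf$samples <- fl
  feats <- pamgame:::csp_features(fit_csp(epf, 6)$W, fl)
  oracle <- suppressWarnings(glm(I(ep$labels == "mi") ~ ., binomial,
                                 data = data.frame(feats)))
  expect_gt(mean((fitted(oracle) > 0.5) == (ep$labels == "mi")), 0.9)
})

test_that("zero-ERD calibration hovers at chance", {
  accs <- vapply(1:3, function(s) {
    ep <- synthetic_mi_epochs(30, 30, erd_depth = 0, seed = 40 + s)
    calibrate_decoder(ep, seed = s)$cv_accuracy
  }, numeric(1))
  expect_true(all(accs > 0.3 & accs < 0.7))
})

test_that("cross-validation folds are stratified", {
  labels <- factor(rep(c("mi", "idle"), each = 30), levels = c("mi", "idle"))
  set.seed(1)
  fold <- pamgame:::stratified_folds(labels, 5)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 12)
    expect_equal(sum(fold == f & labels == "mi"), 6)
  }
})

test_that("a two-second window yields 32 decisions in [0, 1]", {
  ep <- synthetic_mi_epochs(12, 12, erd_depth = 0.8, seed = 33)
  dec <- calibrate_decoder(ep, folds = 3, seed = 33)
  sig <- synthetic_window_signal("mi", erd_depth = 0.8, window = 2,
                                 preroll = 1)
  tr <- stream_decode(dec, sig)
  expect_length(tr, 32)
  expect_true(all(tr >= 0 & tr <= 1))

  # idle signal scores low for a well-calibrated model
  sigi <- synthetic_window_signal("idle", erd_depth = 0.8, window = 2,
                                  preroll = 1)
  expect_lt(median(stream_decode(dec, sigi)), 0.5)

  # constant signal: every buffer identical, every decision identical
  flat <- matrix(0, 7, 500)
  trf <- stream_decode(dec, flat, preroll = 1)
  expect_equal(length(unique(round(as.numeric(trf), 12))), 1)

  expect_error(stream_decode(dec, matrix(0, 7, 5)), "shorter")
})

test_that("dwell detection matches its definition and brute force", {
  need8 <- list(threshold = 0.5, dwell = 0.5, decision_rate = 16)
  det <- function(v) detect_mi(v, threshold = 0.5, dwell = 0.5,
                               decision_rate = 16)

  r <- det(c(rep(0.9, 8), rep(0, 24)))
  expect_true(r$detected)
  expect_equal(r$latency, 0.5)

  expect_false(det(rep(0, 32))$detected)

  # a 7-run, a dip, then an 8-run: latency comes from the second run
  v <- c(rep(0.9, 7), 0.4, rep(0.9, 8), rep(0, 16))
  r <- det(v)
  expect_true(r$detected)
  expect_equal(r$latency, 16 / 16)

  expect_error(detect_mi(numeric(0), threshold = 0.5, dwell = 0.5,
                         decision_rate = 16), "empty")

  # equivalence with explicit window enumeration on random traces
  set.seed(77)
  for (i in 1:1000) {
    v <- runif(32)
    a <- det(v)
    b <- brute_force_detect(v, 0.5, 8, 16)
    expect_identical(a$detected, b$detected)
    expect_identical(a$latency, b$latency)
  }
})

test_that("raising the threshold never creates a detection", {
  set.seed(78)
  n_hi <- 0
  for (i in 1:300) {
    # smoothed random walk, so both thresholds see detections sometimes
    v <- plogis(cumsum(rnorm(32, 0, 0.8)))
    lo <- detect_mi(v, threshold = 0.4, dwell = 0.5, decision_rate = 16)
    hi <- detect_mi(v, threshold = 0.7, dwell = 0.5, decision_rate = 16)
    expect_true(lo$detected || !hi$detected)
    n_hi <- n_hi + hi$detected
  }
  expect_gt(n_hi, 0)     # the property was exercised, not vacuous
})

test_that("end-to-end simulated users span the expected control range", {
  # strong ERD: reliable control after threshold tuning
  ep <- synthetic_mi_epochs(30, 30, erd_depth = 0.8, seed = 51)
  dec <- calibrate_decoder(ep, seed = 51)
  set.seed(51)
  dec <- tune_threshold(dec, erd_depth = 0.8)
  u <- decoder_user(dec, erd_depth = 0.8)
  expect_gt(mean(vapply(1:25, function(i) u(), logical(1))), 0.8)

  # no ERD: the tuned decoder succeeds only sporadically
  ep0 <- synthetic_mi_epochs(30, 30, erd_depth = 0, seed = 52)
  dec0 <- calibrate_decoder(ep0, seed = 52)
  set.seed(52)
  dec0 <- tune_threshold(dec0, erd_depth = 0)
  u0 <- decoder_user(dec0, erd_depth = 0)
  rate0 <- mean(vapply(1:25, function(i) u0(), logical(1)))
  expect_gte(rate0, 0.04)    # sporadic false activations do occur
  expect_lte(rate0, 0.5)
})
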