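#' Band-pass filter a multichannel signal
#'
#' Zero-phase 8-30 Hz Butterworth filtering (order `order`, applied
#' forward-backward), the standard pre-processing step that isolates the
#' mu and beta bands before spatial filtering.
#'
#' @param x channel x time matrix, or epoch x channel x time array.
#' @param rate sampling rate in Hz.
#' @param band passband edges in Hz.
#' @param order filter order.
#' @keywords internal
bandpass_mu_beta <- function(x, rate, band = c(8, 30), order = 5) {
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  apply_rowwise <- function(m) t(apply(m, 1, function(ch) signal::filtfilt(bf, ch)))
  if (length(dim(x)) == 3) {
    out <- x
    for (e in seq_len(dim(x)[1])) out[e, , ] <- apply_rowwise(x[e, , ])
    out
  } else {
    apply_rowwise(x)
  }
}

epoch_cov <- function(m, loading = 1e-6) {
  # spatial covariance normalized by total power, with diagonal loading
  cc <- tcrossprod(m) / sum(m * m)
  cc + diag(loading * sum(diag(cc)) / nrow(cc), nrow(cc))
}

#' Common spatial patterns
#'
#' Fits CSP filters to a two-class `epoch_set`: the rows of the returned
#' projection matrix are generalized eigenvectors of the two class-average
#' covariance matrices, ordered by eigenvalue, taking `n_components / 2`
#' from each end of the spectrum. The filters simultaneously diagonalize
#' both class covariances and whiten their sum, so projected variance is
#' maximally discriminative between classes.
#'
#' @param epochs an `epoch_set` with both classes present.
#' @param n_components even number of spatial filters to keep (half from
#'   each end of the eigenvalue spectrum).
#' @param loading diagonal loading added to each covariance, as a fraction
#'   of its mean eigenvalue, for numerical stability.
#' @return list of class `csp` with `W` (n_components x n_channels filter
#'   matrix), `eigenvalues` (all, sorted decreasing), `selected` (indices
#'   kept), and `channels`.
#' @export
fit_csp <- function(epochs, n_components = 6, loading = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_components %% 2 != 0) stop("n_components must be even")
  n_chan <- dim(epochs$samples)[2]
  if (n_components > n_chan) stop("more components than channels")
  cls <- levels(epochs$labels)
  if (any(tabulate(epochs$labels, 2) == 0)) stop("both classes must be present")

  class_cov <- function(lv) {
    idx <- which(epochs$labels == lv)
    covs <- lapply(idx, function(e) epoch_cov(epochs$samples[e, , ], loading))
    Reduce(`+`, covs) / length(covs)
  }
  C1 <- class_cov(cls[1])
  C2 <- class_cov(cls[2])

  # whiten the composite covariance, then rotate within the whitened space
  eg <- eigen(C1 + C2, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    stop("pooled covariance is numerically singular")
  }
  P <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  S1 <- P %*% C1 %*% t(P)
  eg2 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)
  W_full <- t(eg2$vectors) %*% P        # rows: filters, eigenvalues decreasing

  half <- n_components / 2
  sel <- c(seq_len(half), n_chan - half + seq_len(half))
  structure(list(W = W_full[sel, , drop = FALSE],
                 eigenvalues = eg2$values, selected = sel,
                 channels = epochs$channels),
            class = "csp")
}

csp_features <- function(W, samples3d) {
  # log-variance of each CSP component, one row per epoch
  t(apply(samples3d, 1, function(ep) {
    proj <- W %*% ep
    log(pmax(apply(proj, 1, stats::var), 1e-300))
  }))
}

stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

two_class_score <- function(lda_fit, feats, positive) {
  # signed distance along the discriminant, oriented so `positive` is high,
  # centered at the midpoint of the projected class means
  proj <- as.matrix(feats) %*% lda_fit$scaling[, 1]
  mu <- lda_fit$means %*% lda_fit$scaling[, 1]
  sgn <- if (mu[positive, 1] >= mu[rownames(mu) != positive, 1]) 1 else -1
  sgn * (proj - mean(mu))
}

#' Calibrate the simulated online MI decoder
#'
#' Runs the full calibration pipeline on labeled epochs: 5th-order
#' Butterworth band-pass (8-30 Hz), CSP spatial filtering, log-variance
#' band-power features, and a linear discriminant. Cross-validated accuracy
#' is estimated with stratified folds in which the band-pass, CSP and LDA
#' are all refit on each training split; the returned model is refit on all
#' epochs.
#'
#' The online score is the logistic of the signed discriminant distance, so
#' it lies in (0, 1) with MI mapping high. Detection then requires the
#' score to dwell above `threshold` for `dwell` consecutive seconds at
#' `decision_rate` decisions per second.
#'
#' @inheritParams fit_csp
#' @param folds number of stratified cross-validation folds.
#' @param seed optional seed controlling the fold assignment.
#' @param threshold probability threshold in (0, 1) the online score must
#'   exceed.
#' @param dwell required consecutive super-threshold time, seconds.
#' @param decision_rate decisions per second of the online stream.
#' @param buffer sliding analysis buffer length in seconds.
#' @param band,order band-pass passband (Hz) and filter order.
#' @return object of class `mi_decoder` with elements `csp`, `lda`,
#'   `cv_accuracy`, and the detection parameters.
#' @examples
#' ep <- synthetic_mi_epochs(20, 20, erd_depth = 0.8, seed = 2)
#' dec <- calibrate_decoder(ep, seed = 2)
#' dec$cv_accuracy
#' @export
calibrate_decoder <- function(epochs, n_components = 6, folds = 5,
                              seed = NULL, threshold = 0.5, dwell = 0.5,
                              decision_rate = 16, buffer = 1,
                              band = c(8, 30), order = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (folds < 2) stop("folds must be at least 2")
  if (any(tabulate(epochs$labels, 2) < folds)) {
    stop("each class needs at least `folds` epochs")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  n_dwell <- dwell * decision_rate
  if (abs(n_dwell - round(n_dwell)) > 1e-9 || n_dwell < 1) {
    stop("dwell x decision_rate must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)

  filtered <- bandpass_mu_beta(epochs$samples, epochs$rate, band, order)
  fepochs <- epochs
  fepochs$samples <- filtered

  fold <- stratified_folds(epochs$labels, folds)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fepochs
    tr$samples <- fepochs$samples[fold != f, , , drop = FALSE]
    tr$labels <- droplevels(fepochs$labels[fold != f])
    csp <- fit_csp(tr, n_components)
    ftr <- csp_features(csp$W, tr$samples)
    if (any(apply(ftr, 2, stats::sd) < 1e-12)) {
      stop("degenerate (zero-variance) calibration features")
    }
    lda <- MASS::lda(ftr, grouping = tr$labels)
    fte <- csp_features(csp$W, fepochs$samples[fold == f, , , drop = FALSE])
    mean(stats::predict(lda, fte)$class == fepochs$labels[fold == f])
  }, numeric(1))

  csp <- fit_csp(fepochs, n_components)
  feats <- csp_features(csp$W, fepochs$samples)
  lda <- MASS::lda(feats, grouping = fepochs$labels)

  structure(list(band = band, order = order, csp = csp, lda = lda,
                 positive_class = "mi",
                 cv_accuracy = mean(acc), cv_fold_accuracy = acc,
                 threshold = threshold, dwell = dwell,
                 decision_rate = decision_rate, buffer = buffer,
                 rate = epochs$rate, channels = epochs$channels),
            class = "mi_decoder")
}

#' @export
print.mi_decoder <- function(x, ...) {
  cat(sprintf(paste0("<mi_decoder> band %g-%g Hz, %d CSP components, ",
                     "CV accuracy %.1f%%\n  threshold %.2f, dwell %.2f s ",
                     "@ %g decisions/s, buffer %g s\n"),
              x$band[1], x$band[2], nrow(x$csp$W), 100 * x$cv_accuracy,
              x$threshold, x$dwell, x$decision_rate, x$buffer))
  invisible(x)
}

#' Online decision stream over a continuous signal
#'
#' Emits one score in \[0, 1\] every `1/decision_rate` seconds, each
#' computed from the trailing analysis buffer (band-pass, CSP projection,
#' log-variance, discriminant, logistic). Near the start of the signal the
#' buffer truncates to the available samples. If `preroll > 0`, decisions
#' are only emitted for times after the preroll, so the trace covers the
#' input window proper while the buffer can reach back into the lead-in.
#'
#' @param model an `mi_decoder`.
#' @param signal channel x time matrix (channels ordered as the montage);
#'   an attribute `preroll` (seconds), as set by
#'   [synthetic_window_signal()], is honoured unless overridden.
#' @param rate sampling rate of `signal` in Hz.
#' @param preroll seconds of lead-in to skip before the first decision.
#' @return object of class `decision_trace`: numeric vector of scores with
#'   attributes `decision_rate` and `t0` (time of the window start).
#' @export
stream_decode <- function(model, signal, rate = model$rate,
                          preroll = attr(signal, "preroll") %||% 0) {
  stopifnot(inherits(model, "mi_decoder"), is.matrix(signal))
  n <- ncol(signal)
  dur <- n / rate
  if (dur - preroll < 1 / model$decision_rate) {
    stop("signal shorter than one decision period after the preroll")
  }
  ks <- seq.int(floor(preroll * model$decision_rate) + 1,
                floor(dur * model$decision_rate))
  buf_n <- round(model$buffer * rate)
  vals <- vapply(ks, function(k) {
    end <- round(k / model$decision_rate * rate)
    beg <- max(1L, end - buf_n + 1L)
    buf <- bandpass_mu_beta(signal[, beg:end, drop = FALSE], rate,
                            model$band, model$order)
    feat <- log(pmax(apply(model$csp$W %*% buf, 1, stats::var), 1e-300))
    score <- two_class_score(model$lda, matrix(feat, 1), model$positive_class)
    stats::plogis(score)
  }, numeric(1))
  structure(vals, decision_rate = model$decision_rate, t0 = preroll,
            class = "decision_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dwell-threshold MI detection on a decision trace
#'
#' Scans the trace left to right for the first run of at least
#' `dwell * decision_rate` consecutive values at or above the threshold
#' (8 decisions for the defaults: 0.5 s at 16 Hz). Latency is the time of
#' the last decision of that first qualifying run, measured from the
#' window start.
#'
#' @param trace a `decision_trace` or plain numeric vector of scores.
#' @param model an `mi_decoder` supplying `threshold`, `dwell` and
#'   `decision_rate`; individual values can be overridden.
#' @param threshold,dwell,decision_rate overrides of the model parameters.
#' @return list with `detected` (logical) and `latency` (seconds, `NA` when
#'   not detected).
#' @export
detect_mi <- function(trace, model = NULL,
                      threshold = model$threshold,
                      dwell = model$dwell,
                      decision_rate = model$decision_rate) {
  if (length(trace) == 0) stop("empty decision trace")
  need <- round(dwell * decision_rate)
  r <- rle(as.numeric(trace) >= threshold)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(list(detected = FALSE, latency = NA_real_))
  first <- hit[1]
  start <- ends[first] - r$lengths[first] + 1
  list(detected = TRUE, latency = (start + need - 1) / decision_rate)
}

#' Simulated users for the trial scheduler
#'
#' `bernoulli_user()` draws trial successes from a fixed conversion rate;
#' `decoder_user()` runs the full pipeline per trial: a fresh synthetic
#' window signal (MI attempt), the online decision stream, and
#' dwell-threshold detection. Both return a zero-argument function drawing
#' from the current RNG stream, suitable for [run_condition()].
#'
#' @param rate per-trial success probability in \[0, 1\].
#' @param decoder a calibrated `mi_decoder`.
#' @param erd_depth,noise_sd signal parameters of the simulated user's EEG.
#' @return function() -> logical (did the trial's MI attempt succeed).
#' @export
bernoulli_user <- function(rate) {
  stopifnot(rate >= 0, rate <= 1)
  function() stats::runif(1) < rate
}

#' @rdname bernoulli_user
#' @param window,preroll window and lead-in lengths in seconds.
#' @export
decoder_user <- function(decoder, erd_depth = 0.5, noise_sd = 1,
                         window = 2, preroll = 1) {
  stopifnot(inherits(decoder, "mi_decoder"))
  function() {
    sig <- synthetic_window_signal("mi", erd_depth = erd_depth,
                                   noise_sd = noise_sd, window = window,
                                   preroll = preroll, rate = decoder$rate)
    detect_mi(stream_decode(decoder, sig), decoder)$detected
  }
}

#' Tune the detection threshold in a short simulated online test
#'
#' Emulates the brief online test run before play: fresh synthetic windows
#' are streamed through the decoder and the probability threshold is
#' chosen on a grid from the resulting detection rates. The default
#' criterion picks the lowest threshold whose false-positive rate on idle
#' windows stays at or under `fpr_target`, keeping false activations rare
#' while leaving the BCI as easy to activate as possible; `"youden"`
#' instead maximizes TPR - FPR on MI plus idle windows (ties going to the
#' higher threshold).
#'
#' @param decoder a calibrated `mi_decoder`.
#' @param erd_depth,noise_sd signal parameters of the simulated user.
#' @param n_windows windows generated per class.
#' @param grid candidate thresholds.
#' @param criterion `"fpr"` (constrain false positives) or `"youden"`.
#' @param fpr_target maximum tolerated idle-window detection rate under
#'   the `"fpr"` criterion.
#' @return the decoder with `threshold` replaced and a `tuning` record
#'   (grid, TPR, FPR) attached.
#' @export
tune_threshold <- function(decoder, erd_depth = 0.5, noise_sd = 1,
                           n_windows = 14, grid = seq(0.05, 0.95, by = 0.05),
                           criterion = c("fpr", "youden"), fpr_target = 0.2) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(decoder, "mi_decoder"))
  traces <- function(kind) replicate(n_windows, stream_decode(
    decoder, synthetic_window_signal(kind, erd_depth = erd_depth,
                                     noise_sd = noise_sd,
                                     rate = decoder$rate)),
    simplify = FALSE)
  rate_at <- function(trs, th) {
    mean(vapply(trs, function(t)
      detect_mi(t, decoder, threshold = th)$detected, logical(1)))
  }
  tr_idle <- traces("idle")
  fpr <- vapply(grid, rate_at, numeric(1), trs = tr_idle)
  tpr <- NULL
  if (criterion == "fpr") {
    ok <- which(fpr <= fpr_target)
    th <- grid[if (length(ok)) min(ok) else length(grid)]
  } else {
    tr_mi <- traces("mi")
    tpr <- vapply(grid, rate_at, numeric(1), trs = tr_mi)
    J <- tpr - fpr
    th <- grid[max(which(J == max(J)))]
  }
  decoder$threshold <- th
  decoder$tuning <- list(criterion = criterion, grid = grid,
                         fpr = fpr, tpr = tpr)
  decoder
}
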