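# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# study table without the transcription-note message
quiet_study_table <- function(...) suppressMessages(load_study_table(...))

# marginal log-likelihood of the ordinal random-intercept model by
# adaptive-free Gauss-Hermite quadrature (default 50 nodes)
gh_loglik <- function(data, response, covariates, group, theta, beta, sigma,
                      nodes = 50) {
  gh <- pracma::gaussHermite(nodes)
  y <- data[[response]]
  X <- if (length(covariates)) as.matrix(data[covariates]) else
    matrix(0, nrow(data), 0)
  eta_fix <- if (ncol(X)) drop(X %*% beta) else rep(0, nrow(data))
  up <- c(theta, Inf)
  lo <- c(-Inf, theta)
  ll <- 0
  for (g in unique(data[[group]])) {
    rows <- which(data[[group]] == g)
    f <- vapply(gh$x, function(t) {
      b <- sqrt(2) * sigma * t
      eta <- eta_fix[rows] + b
      prod(plogis(up[y[rows]] - eta) - plogis(lo[y[rows]] - eta))
    }, numeric(1))
    ll <- ll + log(sum(gh$w * f) / sqrt(pi))
  }
  ll
}

# brute-force dwell detection: check every window of `need` consecutive
# decisions explicitly
brute_force_detect <- function(values, threshold, need, decision_rate) {
  n <- length(values)
  if (n >= need) {
    for (s in seq_len(n - need + 1)) {
      if (all(values[s:(s + need - 1)] >= threshold)) {
        return(list(detected = TRUE,
                    latency = (s + need - 1) / decision_rate))
      }
    }
  }
  list(detected = FALSE, latency = NA_real_)
}

# mean band power in [lo, hi] Hz from the raw periodogram
band_power <- function(x, rate, lo = 8, hi = 30) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0, detrend = FALSE)
  mean(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

# exhaustive best-first model search over term subsets of size <= depth,
# mirroring forward stepwise admission rules
exhaustive_stepwise <- function(null_formula, candidates, data, alpha = 0.05,
                                depth = 2, ...) {
  base <- clmm(null_formula, data, ...)
  selected <- character()
  current <- base
  for (d in seq_len(depth)) {
    remaining <- sort(setdiff(candidates, selected))
    if (!length(remaining)) break
    fits <- lapply(remaining, function(term) {
      f <- pamgame:::add_term(null_formula, c(selected, term))
      clmm(f, data, ...)
    })
    ps <- vapply(fits, function(f) lr_test(current, f)$p, numeric(1))
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    lrs <- vapply(fits, function(f) lr_test(current, f)$lr, numeric(1))
    ok <- ps < alpha
    if (!any(ok)) break
    ord <- order(ifelse(ok, aics, Inf), -lrs, remaining)
    selected <- c(selected, remaining[ord[1]])
    current <- fits[[ord[1]]]
  }
  selected
}
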