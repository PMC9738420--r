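## Cumulative link (proportional odds) models with a subject random
## intercept, maximum likelihood via the Laplace approximation.
##
## Model: P(Y_ij <= k | b_i) = logit^{-1}(theta_k - x_ij' beta - b_i),
## b_i ~ N(0, sigma^2), thresholds theta_1 < ... < theta_{J-1}.
## The marginal likelihood integrates b_i out per subject; the integral is
## approximated by a second-order (Laplace) expansion at the conditional
## mode, found by Newton's method (the conditional log-density is concave
## in b for the logistic link).

# stable cell probability and derivatives of u = log P(y = k) wrt eta,
# where the cell bounds are a0 = theta_{k-1} - eta, a1 = theta_k - eta
cell_terms <- function(a0, a1) {
  swap <- (a0 + a1) > 0            # compute in the better tail
  p <- ifelse(swap, stats::plogis(-a0) - stats::plogis(-a1),
              stats::plogis(a1) - stats::plogis(a0))
  p <- pmax(p, 1e-300)
  f0 <- stats::dlogis(a0); f1 <- stats::dlogis(a1)
  F0 <- stats::plogis(a0); F1 <- stats::plogis(a1)
  N <- f1 - f0
  list(logp = log(p),
       du = -N / p,
       d2u = ((f1 * (1 - 2 * F1) - f0 * (1 - 2 * F0)) * p - N^2) / p^2)
}

# negative log marginal likelihood factory; parameters are
# (theta_1, log diff(theta), beta, log sigma); modes warm-started
clmm_nll_factory <- function(y, X, grp, J, random) {
  G <- if (random) max(grp) else 0L
  p <- ncol(X)
  bcur <- rep(0, G)
  function(par) {
    th <- cumsum(c(par[1], exp(par[1 + seq_len(J - 2)])))
    beta <- par[(J - 1) + seq_len(p)]
    eta0 <- if (p) drop(X %*% beta) else numeric(length(y))
    thL <- c(-Inf, th)[y]
    thU <- c(th, Inf)[y]
    if (!random) {
      ct <- cell_terms(thL - eta0, thU - eta0)
      return(-sum(ct$logp))
    }
    sigma <- exp(par[J + p])
    b <- bcur
    for (it in 1:100) {                   # joint Newton over all subjects
      eta <- eta0 + b[grp]
      ct <- cell_terms(thL - eta, thU - eta)
      g1 <- rowsum(ct$du, grp)[, 1] - b / sigma^2
      g2 <- rowsum(ct$d2u, grp)[, 1] - 1 / sigma^2
      step <- g1 / g2
      b <- b - step
      if (max(abs(step)) < 1e-10) break
    }
    bcur <<- b
    eta <- eta0 + b[grp]
    ct <- cell_terms(thL - eta, thU - eta)
    h <- -(rowsum(ct$d2u, grp)[, 1] - 1 / sigma^2)
    -(sum(ct$logp) - sum(b^2) / (2 * sigma^2) - G * log(sigma) -
        0.5 * sum(log(h)))
  }
}

parse_clmm_formula <- function(formula) {
  labs <- attr(stats::terms(formula), "term.labels")
  bar <- grepl("|", labs, fixed = TRUE)
  if (sum(bar) > 1) stop("at most one random term (1 | group) is supported")
  group <- NULL
  if (any(bar)) {
    m <- regmatches(labs[bar], regexec("^1 *\\| *(.+)$", labs[bar]))[[1]]
    if (length(m) != 2) {
      stop("random term must be a plain intercept: (1 | group)")
    }
    group <- trimws(m[2])
  }
  fixed <- if (any(!bar)) {
    stats::reformulate(labs[!bar], response = formula[[2]])
  } else {
    stats::as.formula(call("~", formula[[2]], 1))
  }
  list(fixed = fixed, group = group)
}

#' Cumulative link mixed model with Laplace-approximated ML
#'
#' Fits an ordinal (proportional odds) logit model with flexible strictly
#' increasing thresholds, optional fixed effects, and an optional subject
#' random intercept written lme4-style in the formula:
#' `rating ~ fish_lost + (1 | participant)`. Without a random term the
#' ordinary cumulative logit model is fitted (used internally for starting
#' values and as the sigma = 0 reference).
#'
#' The marginal likelihood integrates the random intercept out per subject
#' with a Laplace approximation at the conditional mode (inner Newton
#' iterations to 1e-10); the outer optimization runs over thresholds (via
#' an increasing reparameterization), fixed effects and log sigma, from
#' multiple deterministic starts, polished by BFGS. Standard errors come
#' from the observed information at the optimum. The parameter count is
#' `k = (J - 1) + p + 1` (thresholds, fixed effects, variance); the
#' variance parameter counts toward `k` even when sigma is fixed at zero,
#' keeping AIC comparable across boundary fits.
#'
#' @param formula response ~ fixed terms + (1 | group). The response is
#'   coerced to an ordered set of levels; a factor keeps its level order.
#' @param data a `data.frame`; rows with missing values in the used
#'   variables are dropped (listwise).
#' @param fix_sigma optional non-negative value freezing the random-
#'   intercept SD (0 gives the fixed-effects fit with the grouping
#'   retained and `k` unchanged).
#' @param starts number of deterministic optimizer starts (jittered around
#'   the fixed-effects solution).
#' @param control list passed to [stats::nlminb()].
#' @return object of class `clmm`: thresholds `theta`, fixed effects
#'   `beta`, random-intercept SD `sigma`, `loglik`, parameter count `k`,
#'   `aic`, the fixed-effect covariance `vcov_beta`, per-effect `se`, `z`
#'   and `p`, conditional modes `ranef`, and bookkeeping (`n`, `J`,
#'   `levels`, `formula`, `boundary` flag).
#' @examples
#' tab <- complete_sessions(load_study_table())
#' fit <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab)
#' summary(fit)
#' @export
clmm <- function(formula, data, fix_sigma = NULL, starts = 3,
                 control = list(eval.max = 2000, iter.max = 1000)) {
  pf <- parse_clmm_formula(formula)
  random <- !is.null(pf$group) && is.null(fix_sigma)

  vars <- unique(c(all.vars(pf$fixed), pf$group))
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  mf <- stats::model.frame(pf$fixed, data)
  yraw <- stats::model.response(mf)
  ylev <- if (is.factor(yraw)) levels(droplevels(yraw)) else sort(unique(yraw))
  y <- as.integer(factor(yraw, levels = ylev))
  J <- length(ylev)
  if (J < 2) stop("response needs at least two observed levels")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  grp <- if (!is.null(pf$group)) as.integer(factor(data[[pf$group]])) else NULL
  if (random && max(grp) < 2) stop("need at least 2 groups for a random intercept")

  nll <- clmm_nll_factory(y, X, grp, J, random)

  # final Newton polishing on the chosen optimum: numerical gradient and
  # observed information, accepted only while it improves the objective
  polish <- function(fn, par, value) {
    for (it in 1:8) {
      g <- num_grad(fn, par)
      if (sqrt(sum(g^2)) < 1e-8) break
      H <- try(stats::optimHess(par, fn), silent = TRUE)
      if (inherits(H, "try-error")) break
      step <- try(solve(H, g), silent = TRUE)
      if (inherits(step, "try-error")) break
      cand <- par - step
      vc <- fn(cand)
      if (!is.finite(vc) || vc > value + 1e-12) break
      par <- cand; value <- vc
    }
    list(par = par, value = value)
  }

  # fixed-effects fit for starting values
  nll_fixed <- clmm_nll_factory(y, X, grp, J, random = FALSE)
  cl <- stats::qlogis(pmin(pmax(
    cumsum(prop.table(tabulate(y, J)))[seq_len(J - 1)], 1e-6), 1 - 1e-6))
  st0 <- c(cl[1], log(pmax(diff(cl), 0.05)), rep(0, p))
  opf <- stats::nlminb(st0, nll_fixed, control = control)
  opf <- stats::optim(opf$par, nll_fixed, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opf <- polish(nll_fixed, opf$par, opf$value)

  if (!random) {
    par <- opf$par
    loglik <- -opf$value
    sigma <- if (is.null(fix_sigma)) NA_real_ else fix_sigma
    k <- (J - 1) + p + if (is.null(pf$group)) 0L else 1L
    if (!is.null(fix_sigma) && fix_sigma > 0) {
      stop("fix_sigma > 0 is not supported; fit the random term freely")
    }
  } else {
    base <- c(opf$par, 0)                     # log sigma start at 0
    jitter <- list(0, c(rep(0.05, J - 1 + p), -0.7),
                   c(rep(-0.05, J - 1 + p), 0.7))
    best <- NULL
    for (s in seq_len(min(starts, length(jitter)))) {
      op <- stats::nlminb(base + jitter[[s]], nll, control = control)
      op <- stats::optim(op$par, nll, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || op$value < best$value) best <- op
    }
    best <- polish(nll, best$par, best$value)
    par <- best$par
    loglik <- -best$value
    sigma <- exp(par[J + p])
    k <- (J - 1) + p + 1L
  }

  th <- cumsum(c(par[1], exp(par[1 + seq_len(J - 2)])))
  beta <- stats::setNames(par[(J - 1) + seq_len(p)], colnames(X))

  vcov_beta <- matrix(NA_real_, p, p, dimnames = list(names(beta), names(beta)))
  se <- z <- pv <- stats::setNames(rep(NA_real_, p), names(beta))
  H <- try(stats::optimHess(par, if (random) nll else nll_fixed), silent = TRUE)
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error")) {
      idx <- (J - 1) + seq_len(p)
      vcov_beta <- Vi[idx, idx, drop = FALSE]
      dimnames(vcov_beta) <- list(names(beta), names(beta))
      se <- sqrt(pmax(diag(vcov_beta), 0))
      z <- beta / se
      pv <- 2 * stats::pnorm(-abs(z))
    }
  }

  ranef <- NULL
  if (random) {
    nll(par)                                  # refresh modes at the optimum
    ranef <- environment(nll)$bcur
  }
  boundary <- random && sigma < 1e-3

  structure(list(theta = th, beta = beta, sigma = sigma,
                 loglik = loglik, k = k, aic = 2 * k - 2 * loglik,
                 vcov_beta = vcov_beta, se = se, z = z, p = pv,
                 ranef = ranef, n = length(y), J = J, levels = ylev,
                 formula = formula, group = pf$group, random = random,
                 fix_sigma = fix_sigma, boundary = boundary,
                 model = data[vars], par = par),
            class = "clmm")
}

num_grad <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, numeric(1))
}

#' Gradient norm of the negative log-likelihood at the optimum
#' @param fit a `clmm` fit.
#' @keywords internal
clmm_grad_norm <- function(fit) {
  pf <- parse_clmm_formula(fit$formula)
  mf <- stats::model.frame(pf$fixed, fit$model)
  y <- as.integer(factor(stats::model.response(mf), levels = fit$levels))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  grp <- if (!is.null(pf$group)) as.integer(factor(fit$model[[pf$group]]))
  nll <- clmm_nll_factory(y, X, grp, fit$J, fit$random)
  sqrt(sum(num_grad(nll, fit$par)^2))
}
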