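#' @export
print.clmm <- function(x, digits = 4, ...) {
  cat("Cumulative link mixed model (logit link, Laplace ML)\n")
  cat("formula:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, J = %d levels, logLik = %.3f, AIC = %.2f (k = %d)\n",
              x$n, x$J, x$loglik, x$aic, x$k))
  if (x$random) {
    cat(sprintf("random intercept (%s): sd = %.4f%s\n", x$group, x$sigma,
                if (x$boundary) " [boundary]" else ""))
  } else if (!is.null(x$fix_sigma)) {
    cat(sprintf("random intercept (%s): sd fixed at %g\n",
                x$group, x$fix_sigma))
  }
  if (length(x$beta)) {
    cat("fixed effects:\n")
    print(round(x$beta, digits))
  }
  invisible(x)
}

#' @export
summary.clmm <- function(object, ...) {
  coefs <- cbind(Estimate = object$beta, `Std. Error` = object$se,
                 `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(fit = object, coefficients = coefs),
            class = "summary.clmm")
}

#' @export
print.summary.clmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (nrow(x$coefficients)) {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coefficients, digits = digits, has.Pvalue = TRUE)
  }
  cat("\nThresholds:\n")
  th <- x$fit$theta
  names(th) <- paste(x$fit$levels[-x$fit$J], x$fit$levels[-1], sep = "|")
  print(round(th, digits))
  invisible(x)
}

#' @export
coef.clmm <- function(object, ...) object$beta

#' @export
logLik.clmm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.clmm <- function(object, ...) object$vcov_beta

#' @export
nobs.clmm <- function(object, ...) object$n

#' Likelihood-ratio test between two nested fits
#'
#' Compares a null model to an alternative that extends it:
#' `LR = 2 (logLik_alt - logLik_null)`, referred to a chi-square with
#' `df = k_alt - k_null`. Both fits must use the same observations.
#'
#' @param null,alt `clmm` fits, `null` nested in `alt`.
#' @return list of class `clmm_lrt`: `lr`, `df`, `p`, and the two AICs.
#' @export
lr_test <- function(null, alt) {
  stopifnot(inherits(null, "clmm"), inherits(alt, "clmm"))
  if (null$n != alt$n) stop("fits use different numbers of observations")
  if (alt$k < null$k) stop("`alt` must be the larger model")
  df <- alt$k - null$k
  if (df == 0 && abs(alt$loglik - null$loglik) > 1e-6) {
    stop("models have equal size but different likelihoods; not nested")
  }
  lr <- max(0, 2 * (alt$loglik - null$loglik))
  p <- if (df >= 1) stats::pchisq(lr, df, lower.tail = FALSE) else 1
  structure(list(lr = lr, df = df, p = p,
                 aic_null = null$aic, aic_alt = alt$aic),
            class = "clmm_lrt")
}

#' @export
print.clmm_lrt <- function(x, ...) {
  cat(sprintf("LR = %.3f, df = %d, p = %.4g (AIC %.2f -> %.2f)\n",
              x$lr, x$df, x$p, x$aic_null, x$aic_alt))
  invisible(x)
}

#' @export
anova.clmm <- function(object, ...) {
  fits <- list(object, ...)
  if (length(fits) < 2) stop("supply at least two fits to compare")
  out <- data.frame(k = vapply(fits, `[[`, 0, "k"),
                    logLik = vapply(fits, `[[`, 0, "loglik"),
                    AIC = vapply(fits, `[[`, 0, "aic"),
                    LR = NA_real_, df = NA_integer_, p = NA_real_)
  for (i in 2:length(fits)) {
    lt <- lr_test(fits[[i - 1]], fits[[i]])
    out$LR[i] <- lt$lr; out$df[i] <- lt$df; out$p[i] <- lt$p
  }
  out
}

#' Category probabilities for new observations
#'
#' Probabilities of each response level at the population level (random
#' intercept at zero).
#'
#' @param object a `clmm` fit.
#' @param newdata data frame with the model covariates; defaults to the
#'   fitting data.
#' @param ... unused.
#' @return matrix, one row per observation, one column per level.
#' @export
predict.clmm <- function(object, newdata = NULL, ...) {
  pf <- parse_clmm_formula(object$formula)
  data <- newdata %||% object$model
  rhs <- stats::delete.response(stats::terms(pf$fixed))
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, data))
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  eta <- if (ncol(X)) drop(X %*% object$beta) else numeric(nrow(data))
  cum <- stats::plogis(outer(eta, object$theta, function(e, t) t - e))
  probs <- cbind(cum, 1)[, c(1, seq_len(object$J - 1) + 1), drop = FALSE] -
    cbind(0, cum)
  colnames(probs) <- object$levels
  probs
}

#' @export
simulate.clmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- object$model
  X <- model_matrix_clmm(object, data)
  eta_fix <- if (ncol(X)) drop(X %*% object$beta) else rep(0, nrow(data))
  grp <- if (object$random) as.integer(factor(data[[object$group]]))
  out <- replicate(nsim, {
    eta_b <- if (object$random) stats::rnorm(max(grp), 0, object$sigma)[grp]
             else 0
    draw_ordinal(object$theta, eta_fix + eta_b)
  }, simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

model_matrix_clmm <- function(object, data) {
  pf <- parse_clmm_formula(object$formula)
  rhs <- stats::delete.response(stats::terms(pf$fixed))
  X <- stats::model.matrix(rhs, stats::model.frame(rhs, data))
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}

# draw ordinal responses given thresholds and linear predictors
draw_ordinal <- function(theta, eta) {
  u <- stats::rlogis(length(eta))
  findInterval(u + eta, theta) + 1L
}

#' Simulate an ordinal mixed-model dataset
#'
#' Draws data from the cumulative logit random-intercept model itself:
#' latent `x beta + b_g + logistic noise` cut at the thresholds. Used for
#' parameter-recovery and oracle checks.
#'
#' @param n_subjects,n_per number of subjects and observations per subject.
#' @param beta fixed-effect coefficient(s) for covariates drawn standard
#'   normal (one column per element).
#' @param sigma random-intercept SD.
#' @param thresholds strictly increasing cut points (default: 6 equally
#'   spaced for a 7-level response).
#' @param seed optional seed.
#' @return data.frame with `y` (integer level), covariates `x1`, ..., and
#'   `subject`.
#' @export
r_clmm_data <- function(n_subjects, n_per, beta = 0.6, sigma = 1,
                        thresholds = seq(-2.5, 2.5, length.out = 6),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects * n_per
  subject <- rep(seq_len(n_subjects), each = n_per)
  X <- matrix(stats::rnorm(n * length(beta)), n)
  colnames(X) <- paste0("x", seq_along(beta))
  eta <- drop(X %*% beta) + stats::rnorm(n_subjects, 0, sigma)[subject]
  out <- data.frame(y = draw_ordinal(thresholds, eta), X, subject = subject)
  out
}

#' AIC forward stepwise selection over candidate fixed effects
#'
#' Starting from the subject-only null model, repeatedly refits with each
#' remaining candidate added, and adds the candidate giving the lowest AIC
#' among those whose likelihood-ratio test against the current model is
#' significant at `alpha`; stops when no candidate qualifies. Ties in AIC
#' break by larger LR, then lexicographic term name.
#'
#' @param null_formula e.g. `rating ~ (1 | participant)`.
#' @param candidates character vector of candidate term names.
#' @param data the dataset (rows with missing used variables dropped per
#'   fit; supply complete rows for comparable likelihoods).
#' @param alpha significance level of the LR test for admission.
#' @param ... passed to [clmm()].
#' @return object of class `clmm_step`: `selected` (terms in order of
#'   admission), `fit` (the final model), and `trace` -- one row per
#'   evaluated model with columns term, step, AIC, logLik, LR, df, p,
#'   admitted.
#' @export
forward_stepwise <- function(null_formula, candidates, data, alpha = 0.05,
                             ...) {
  current <- clmm(null_formula, data, ...)
  current_terms <- character()
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- sort(setdiff(candidates, current_terms))
    if (length(remaining) == 0) break
    evals <- lapply(remaining, function(term) {
      f <- add_term(null_formula, c(current_terms, term))
      fit <- clmm(f, data, ...)
      lt <- lr_test(current, fit)
      list(term = term, fit = fit, lr = lt)
    })
    for (e in evals) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, term = e$term, AIC = e$fit$aic, logLik = e$fit$loglik,
        LR = e$lr$lr, df = e$lr$df, p = e$lr$p, admitted = FALSE)
    }
    ok <- Filter(function(e) e$lr$p < alpha, evals)
    if (length(ok) == 0) break
    key <- vapply(ok, function(e) e$fit$aic, 0)
    best <- ok[order(key,
                     -vapply(ok, function(e) e$lr$lr, 0),
                     vapply(ok, function(e) e$term, ""))][[1]]
    for (i in seq_along(trace)) {
      if (trace[[i]]$step == step && trace[[i]]$term == best$term) {
        trace[[i]]$admitted <- TRUE
      }
    }
    current <- best$fit
    current_terms <- c(current_terms, best$term)
  }
  structure(list(selected = current_terms, fit = current,
                 trace = do.call(rbind, trace)),
            class = "clmm_step")
}

add_term <- function(null_formula, terms) {
  pf <- parse_clmm_formula(null_formula)
  rand <- if (!is.null(pf$group)) sprintf("(1 | %s)", pf$group)
  stats::as.formula(paste(deparse(null_formula[[2]]), "~",
                          paste(c(terms, rand), collapse = " + ")))
}

#' @export
print.clmm_step <- function(x, ...) {
  cat("Forward stepwise (AIC with LR admission)\n")
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(null model)", "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}
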