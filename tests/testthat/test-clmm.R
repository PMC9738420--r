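tab <- complete_sessions(quiet_study_table())

test_that("a null covariate reduces to the empirical cumulative logits", {
  d <- data.frame(y = rep(1:5, times = c(4, 6, 10, 6, 4)), x = 0)
  fit <- clmm(y ~ x, d)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-5)
  # closed form: thresholds are logits of the cumulative frequencies
  cum <- cumsum(c(4, 6, 10, 6, 4)) / 30
  expect_equal(fit$theta, qlogis(cum[1:4]), tolerance = 1e-5)
})

test_that("the optimizer reaches a stationary point", {
  fit <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab)
  expect_lt(pamgame:::clmm_grad_norm(fit), 1e-6)
  fitf <- clmm(perceived_control_level ~ fish_lost, tab)
  expect_lt(pamgame:::clmm_grad_norm(fitf), 1e-6)
})

test_that("a binary response coincides with logistic regression", {
  d <- r_clmm_data(1, 200, beta = 0.8, sigma = 0, thresholds = 0.3, seed = 7)
  fit <- clmm(y ~ x1, d)
  oracle <- glm(I(y == 2) ~ x1, binomial, d)
  expect_equal(unname(coef(fit)), unname(coef(oracle)[2]), tolerance = 1e-4)
  expect_equal(fit$theta, -unname(coef(oracle)[1]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
})

test_that("the fixed-effects path agrees with the polr oracle", {
  fit <- clmm(perceived_control_level ~ fish_lost + positive_feedback, tab)
  oracle <- MASS::polr(factor(perceived_control_level) ~ fish_lost +
                         positive_feedback, data = tab)
  expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-5)
})

test_that("sigma fixed at zero matches the fixed-effects likelihood", {
  f0 <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab,
             fix_sigma = 0)
  fx <- clmm(perceived_control_level ~ fish_lost, tab)
  expect_equal(f0$loglik, fx$loglik, tolerance = 1e-6)
  expect_equal(f0$k, fx$k + 1L)      # the variance still counts toward k
})

test_that("the marginal likelihood is an exact Laplace approximation", {
  # independent Laplace oracle: per-subject 1-D mode search by optimize()
  # and a central-difference curvature, nothing shared with the package
  manual_laplace <- function(d, th, beta, sigma) {
    up <- c(th, Inf); lo <- c(-Inf, th)
    ll <- 0
    for (g in unique(d$subject)) {
      rows <- which(d$subject == g)
      lg <- function(b) {
        eta <- d$x1[rows] * beta + b
        sum(log(plogis(up[d$y[rows]] - eta) - plogis(lo[d$y[rows]] - eta))) +
          dnorm(b, 0, sigma, log = TRUE)
      }
      bhat <- optimize(function(b) -lg(b), c(-10, 10), tol = 1e-12)$minimum
      h <- 1e-4
      d2 <- (lg(bhat + h) - 2 * lg(bhat) + lg(bhat - h)) / h^2
      ll <- ll + lg(bhat) + 0.5 * log(2 * pi) - 0.5 * log(-d2)
    }
    ll
  }
  for (s in 1:3) {
    d <- r_clmm_data(10, 4, beta = 0.6, sigma = 1, seed = 40 + s)
    fit <- clmm(y ~ x1 + (1 | subject), d)
    if (fit$sigma < 1e-4) next          # boundary fit: Laplace is exact
    expect_lt(abs(fit$loglik -
                    manual_laplace(d, fit$theta, fit$beta, fit$sigma)),
              1e-5)
  }
})

test_that("the Laplace likelihood tracks Gauss-Hermite quadrature", {
  # the intrinsic Laplace error shrinks with per-subject information:
  # within ~0.15 at four observations per subject, within 0.05 at twelve
  for (s in 1:3) {
    d4 <- r_clmm_data(10, 4, beta = 0.6, sigma = 1, seed = 40 + s)
    f4 <- clmm(y ~ x1 + (1 | subject), d4)
    gap4 <- abs(f4$loglik - gh_loglik(d4, "y", "x1", "subject", f4$theta,
                                      f4$beta, f4$sigma, nodes = 50))
    expect_lt(gap4, 0.2)
    d12 <- r_clmm_data(10, 12, beta = 0.6, sigma = 1, seed = 40 + s)
    f12 <- clmm(y ~ x1 + (1 | subject), d12)
    gap12 <- abs(f12$loglik - gh_loglik(d12, "y", "x1", "subject",
                                        f12$theta, f12$beta, f12$sigma,
                                        nodes = 50))
    expect_lt(gap12, 0.05)
  }
})

test_that("AIC bookkeeping and the likelihood-ratio test are consistent", {
  f1 <- clmm(frustration_level ~ fish_lost + (1 | participant), tab)
  expect_equal(f1$aic, 2 * f1$k - 2 * f1$loglik)
  expect_equal(f1$k, (f1$J - 1) + 1 + 1)
  expect_equal(AIC(f1), f1$aic)

  f0 <- clmm(frustration_level ~ (1 | participant), tab)
  lt <- lr_test(f0, f1)
  expect_equal(lt$lr, 2 * (f1$loglik - f0$loglik))
  expect_equal(lt$df, 1)
  expect_equal(lt$p, pchisq(lt$lr, 1, lower.tail = FALSE))

  # a model against itself: no evidence
  ltt <- lr_test(f1, f1)
  expect_equal(ltt$lr, 0)
  expect_equal(ltt$p, 1)

  an <- anova(f0, f1)
  expect_equal(an$LR[2], lt$lr)
})

test_that("monotone relabeling of the response leaves the fit invariant", {
  f1 <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab)
  tab2 <- tab
  relabel <- c(1, 2, 4, 10, 11, 50, 100)     # strictly increasing map
  tab2$perceived_control_level <- relabel[tab$perceived_control_level]
  f2 <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab2)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-5)
  expect_equal(f2$aic, f1$aic, tolerance = 1e-4)
  expect_equal(unname(coef(f2)), unname(coef(f1)), tolerance = 1e-4)
})

test_that("predicted category probabilities are proper", {
  fit <- clmm(perceived_control_level ~ fish_lost + (1 | participant), tab)
  pr <- predict(fit)
  expect_equal(dim(pr), c(71L, 7L))
  expect_equal(unname(rowSums(pr)), rep(1, 71))
  expect_true(all(pr >= 0))
  # more lost fish shifts mass toward low perceived control
  lo <- predict(fit, data.frame(fish_lost = 0))
  hi <- predict(fit, data.frame(fish_lost = 6))
  expect_gt(hi[1, 1], lo[1, 1])
})

test_that("simulation and refitting recover the generating parameters", {
  d <- r_clmm_data(60, 6, beta = 0.7, sigma = 1, seed = 99)
  fit <- clmm(y ~ x1 + (1 | subject), d, starts = 1)
  expect_lt(abs(unname(coef(fit)) - 0.7), 0.25)
  expect_lt(abs(fit$sigma - 1), 0.5)

  # simulate() draws from the fitted model with the right support
  y2 <- simulate(fit, seed = 1)
  expect_true(all(y2 %in% 1:7))
  expect_equal(length(y2), nrow(d))
})

test_that("forward stepwise matches exhaustive best-first search", {
  candidates <- c("fish_lost", "fish_caught", "positive_feedback",
                  "mi_conversion_rate")
  st <- forward_stepwise(perceived_control_level ~ (1 | participant),
                         candidates, tab, starts = 1)
  expect_equal(st$selected[1], "fish_lost")
  oracle <- exhaustive_stepwise(perceived_control_level ~ (1 | participant),
                                candidates, tab, depth = 2, starts = 1)
  expect_identical(st$selected[seq_along(oracle)][1:min(2, length(oracle))],
                   oracle[1:min(2, length(oracle))])

  # empty candidate set: the trace holds only the null model
  st0 <- forward_stepwise(perceived_control_level ~ (1 | participant),
                          character(0), tab, starts = 1)
  expect_length(st0$selected, 0)
  expect_null(st0$trace)
  expect_equal(st0$fit$k, 7L)    # 6 thresholds + variance, no fixed effect
})
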