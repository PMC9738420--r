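test_that("condition plans carry 30% specials, shuffled", {
  for (pam in c("augmented_success", "input_override", "mitigated_failure")) {
    plan <- plan_condition(pam, seed = 3)
    expect_length(plan, 20)
    expect_equal(sum(plan == "special"), 6)
  }
  expect_true(all(plan_condition("normal", seed = 3) == "normal"))

  # different seeds: same multiset of behaviors, typically different order
  p1 <- plan_condition("input_override", seed = 1)
  p2 <- plan_condition("input_override", seed = 2)
  expect_equal(sort(unclass(p1)), sort(unclass(p2)))

  # non-integral help targets round half up
  expect_equal(sum(plan_condition("input_override", n_trials = 10,
                                  help_target = 0.25, seed = 1) == "special"),
               3)
})

test_that("attempt resolution follows the outcome-change taxonomy", {
  cases <- list(
    list("normal", "normal", TRUE, "positive", "Positive (No Change)"),
    list("normal", "normal", FALSE, "negative", "Negative (No Change)"),
    list("reject", "input_override", TRUE, "negative", "Positive to Negative"),
    list("reject", "input_override", FALSE, "negative", "Negative (No Change)"),
    list("special", "input_override", FALSE, "positive",
         "Negative to Positive (IO)"),
    list("special", "input_override", TRUE, "positive",
         "Positive to Positive (IO)"),
    list("special", "mitigated_failure", FALSE, "neutral",
         "Negative to Neutral (MF)"),
    list("special", "mitigated_failure", TRUE, "neutral",
         "Positive to Neutral (MF)"),
    list("special", "augmented_success", TRUE, "extra_positive",
         "Positive to Extra Positive (AS)"))
  for (cs in cases) {
    out <- resolve_attempt(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(out$feedback, cs[[4]])
    expect_equal(out$change_label, cs[[5]])
  }

  # a failed augmented success resolves as a normal failure, deferring help
  out <- resolve_attempt("special", "augmented_success", FALSE)
  expect_equal(out$feedback, "negative")
  expect_true(out$defer_special)
  expect_false(out$special_delivered)

  # deployment mode: IO/MF only fire on failure
  out <- resolve_attempt("special", "input_override", TRUE, "deployment")
  expect_equal(out$change_label, "Positive (No Change)")
  expect_true(out$defer_special)

  expect_error(resolve_attempt("special", "normal", TRUE), "reference")
})

test_that("rescheduling keeps the owed special count", {
  plan <- plan_condition("augmented_success", seed = 9)
  n_special <- sum(plan == "special")
  i <- which(plan == "special")[1]
  plan[i] <- "normal"
  set.seed(1)
  plan2 <- replan_after_failure(plan, i)
  expect_equal(sum(plan2 == "special"), n_special)
  expect_true(all(which(unclass(plan2) != unclass(plan)) > i))

  # no slots left: the special is dropped and logged
  tail_plan <- plan_condition("augmented_success", seed = 10)
  tail_plan[1:20] <- "normal"
  out <- replan_after_failure(tail_plan, 20)
  expect_equal(attr(out, "dropped_specials"), 1L)
})

test_that("an always-failing user never receives augmented success", {
  for (s in 1:25) {
    run <- run_condition("augmented_success", bernoulli_user(0), seed = s)
    expect_equal(run$urn[["special"]], 0L)
    expect_equal(sum(run$trials$special), 0)
  }
})

test_that("the control cap holds for perfect users, stays inert otherwise", {
  for (pam in c("augmented_success", "input_override", "mitigated_failure")) {
    for (s in 1:50) {
      run <- run_condition(pam, bernoulli_user(1), seed = 400 + s)
      expect_lte(summarize_condition(run)$positive_feedback, 0.75)
    }
  }
  # a weak user never triggers forced rejections
  for (s in 1:20) {
    run <- run_condition("input_override", bernoulli_user(0.1), seed = s)
    expect_equal(sum(run$trials$behavior == "reject"), 0)
  }
  # reference condition: cap machinery never engages
  run <- run_condition("normal", bernoulli_user(1), seed = 2)
  s0 <- summarize_condition(run)
  expect_equal(s0$positive_feedback, 1)
})

test_that("reference condition only produces unchanged outcomes", {
  for (s in 1:10) {
    run <- run_condition("normal", bernoulli_user(runif(1)), seed = 600 + s)
    expect_true(all(run$trials$change_label %in%
                      c("Positive (No Change)", "Negative (No Change)")))
    sm <- summarize_condition(run)
    expect_equal(sm$positive_feedback, sm$mi_conversion_rate)
    expect_equal(sm$pam_rate, 0)
  }
})

test_that("specials never outnumber remaining slots", {
  for (s in 1:20) {
    run <- run_condition("augmented_success", bernoulli_user(0.5),
                         seed = 700 + s)
    # delivered + dropped never exceeds the planned quota
    delivered <- run$urn[["special"]]
    dropped <- attr(run$plan, "dropped_specials")
    if (is.null(dropped)) dropped <- 0L
    expect_gte(delivered, 0L)
    expect_lte(dropped + delivered, 6L)
  }
})

test_that("condition order is a Latin-square rotation after the reference", {
  expect_equal(condition_order(0),
               c("normal", "augmented_success", "input_override",
                 "mitigated_failure"))
  pos <- sapply(0:2, function(i) condition_order(i)[2:4])
  for (p in 1:3) expect_setequal(pos[p, ], c("augmented_success",
                                             "input_override",
                                             "mitigated_failure"))
  expect_identical(condition_order(3), condition_order(0))
})
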