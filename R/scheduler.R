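PAM_KINDS <- c("normal", "augmented_success", "input_override",
               "mitigated_failure")

#' Condition order for a participant
#'
#' The reference (no-help) condition always comes first; the three PAM
#' conditions follow a 3x3 Latin-square rotation indexed by
#' `participant_index` modulo 3, so across any three consecutive
#' participants each PAM appears once in each position.
#'
#' @param participant_index zero-based participant index.
#' @return character vector of four condition names.
#' @export
condition_order <- function(participant_index) {
  stopifnot(participant_index >= 0)
  pams <- c("augmented_success", "input_override", "mitigated_failure")
  k <- participant_index %% 3
  c("normal", pams[(seq_len(3) + k - 1) %% 3 + 1])
}

#' Plan the trial behaviors of one condition
#'
#' For a PAM condition, `round(help_target * n_trials)` special (help)
#' trials (rounding half up) are shuffled uniformly among the normal
#' trials; the reference condition is all normal. Forced rejections are not
#' planned up front -- they are inserted adaptively by the control cap
#' during play.
#'
#' @param pam one of `"normal"`, `"augmented_success"`, `"input_override"`,
#'   `"mitigated_failure"`.
#' @param n_trials trials per condition.
#' @param help_target fraction of special trials in PAM conditions.
#' @param seed optional seed for the shuffle.
#' @return object of class `condition_plan`: character vector of behaviors
#'   (`"normal"`/`"special"`) with attributes `pam` and `n_special`.
#' @export
plan_condition <- function(pam, n_trials = 20, help_target = 0.30,
                           seed = NULL) {
  pam <- match.arg(pam, PAM_KINDS)
  if (!is.null(seed)) set.seed(seed)
  behaviors <- rep("normal", n_trials)
  n_special <- 0L
  if (pam != "normal") {
    n_special <- as.integer(floor(help_target * n_trials + 0.5))
    behaviors[sample.int(n_trials, n_special)] <- "special"
  }
  structure(behaviors, pam = pam, n_special = n_special,
            class = "condition_plan")
}

#' Resolve one trial attempt against its planned behavior
#'
#' Maps (behavior, PAM, genuine attempt outcome) to the feedback delivered
#' and an outcome-change label. Rejection trials override successful
#' attempts with negative feedback. In experiment mode, input-override and
#' mitigated-failure specials disregard the user's input; augmented success
#' always requires a genuine success (a failed AS trial resolves as a
#' normal failure and the special is owed to a later slot). In deployment
#' mode IO/MF specials also only trigger on failure, a success resolving
#' normally with the special deferred.
#'
#' @param behavior `"normal"`, `"special"` or `"reject"`.
#' @param pam the condition's PAM kind.
#' @param attempt logical: did the user's MI attempt genuinely succeed.
#' @param mode `"experiment"` (specials fire regardless of input) or
#'   `"deployment"` (IO/MF fire only on failure).
#' @return list with `feedback`, `change_label`, `special_delivered`, and
#'   `defer_special` (the special must be rescheduled).
#' @export
resolve_attempt <- function(behavior, pam, attempt,
                            mode = c("experiment", "deployment")) {
  mode <- match.arg(mode)
  behavior <- match.arg(behavior, c("normal", "special", "reject"))
  pam <- match.arg(pam, PAM_KINDS)
  if (behavior == "special" && pam == "normal") {
    stop("special trial scheduled in the reference condition")
  }
  res <- function(feedback, label, special = FALSE, defer = FALSE) {
    list(feedback = feedback, change_label = label,
         special_delivered = special, defer_special = defer)
  }
  if (behavior == "normal") {
    return(if (attempt) res("positive", "Positive (No Change)")
           else res("negative", "Negative (No Change)"))
  }
  if (behavior == "reject") {
    return(if (attempt) res("negative", "Positive to Negative")
           else res("negative", "Negative (No Change)"))
  }
  # special
  switch(pam,
    augmented_success =
      if (attempt) res("extra_positive", "Positive to Extra Positive (AS)",
                       special = TRUE)
      else res("negative", "Negative (No Change)", defer = TRUE),
    input_override =
      if (!attempt) res("positive", "Negative to Positive (IO)", special = TRUE)
      else if (mode == "experiment")
        res("positive", "Positive to Positive (IO)", special = TRUE)
      else res("positive", "Positive (No Change)", defer = TRUE),
    mitigated_failure =
      if (!attempt) res("neutral", "Negative to Neutral (MF)", special = TRUE)
      else if (mode == "experiment")
        res("neutral", "Positive to Neutral (MF)", special = TRUE)
      else res("positive", "Positive (No Change)", defer = TRUE))
}

#' Reschedule a special trial that failed to trigger
#'
#' When a special could not fire (an augmented success the user failed to
#' produce, or an IO/MF special skipped in deployment mode), it is
#' re-inserted uniformly at random into one of the remaining normal slots.
#' If no normal slot remains the special is dropped and the deficit
#' recorded on the plan.
#'
#' @param plan a `condition_plan`.
#' @param current index of the trial that just resolved.
#' @return the updated plan (attribute `dropped_specials` counts specials
#'   that could not be rescheduled).
#' @export
replan_after_failure <- function(plan, current) {
  future_normal <- which(unclass(plan) == "normal" &
                           seq_along(plan) > current)
  if (length(future_normal) == 0) {
    attr(plan, "dropped_specials") <-
      (attr(plan, "dropped_specials") %||% 0L) + 1L
    return(plan)
  }
  slot <- future_normal[sample.int(length(future_normal), 1L)]
  plan[slot] <- "special"
  plan
}

#' Enforce the 70% experienced-control cap
#'
#' Called after every resolved trial in helped conditions. Forced
#' rejections are inserted once the player is succeeding above the target
#' control rate: with the default `"above_target"` trigger, conversion
#' starts only when the positives delivered so far exceed `cap` times the
#' trials played by at least one full trial, so a weak player for whom
#' the cap is unreachable never sees a rejection. Once triggered (always,
#' under the `"eager"` trigger), the worst case is projected forward --
#' positives so far plus every future slot that could still deliver
#' positive feedback (normal slots, and IO/AS specials; MF specials
#' deliver neutral, rejects negative) -- and upcoming normal slots are
#' converted to rejections while that projection exceeds
#' `floor(cap * n) + 1`, so a player succeeding above the target finishes
#' at or below `cap + 1/n`. Special slots are never converted.
#'
#' @param plan a `condition_plan`.
#' @param delivered_positive count of positive/extra-positive trials so far.
#' @param current index of the trial that just resolved.
#' @param control_cap the cap fraction.
#' @param trigger `"above_target"` (convert only once observed control
#'   exceeds the cap with one trial's margin) or `"eager"` (hold the
#'   worst-case bound from the first trial, which plants rejections for
#'   every player).
#' @param slot_choice which upcoming normal slot to convert first:
#'   `"random"` draws uniformly, `"earliest"` converts in order.
#' @return the updated plan.
#' @export
enforce_control_cap <- function(plan, delivered_positive, current,
                                control_cap = 0.70,
                                trigger = c("above_target", "eager"),
                                slot_choice = c("random", "earliest")) {
  trigger <- match.arg(trigger)
  slot_choice <- match.arg(slot_choice)
  pam <- attr(plan, "pam")
  if (pam == "normal") return(plan)        # cap applies to helped conditions
  if (trigger == "above_target" &&
      delivered_positive < control_cap * current + 1) {
    return(plan)
  }
  n <- length(plan)
  allowed <- floor(control_cap * n) + 1L
  special_positive <- pam %in% c("input_override", "augmented_success")
  repeat {
    future <- seq_along(plan) > current
    future_max <- sum(future & unclass(plan) == "normal") +
      if (special_positive) sum(future & unclass(plan) == "special") else 0L
    if (delivered_positive + future_max <= allowed) break
    candidates <- which(future & unclass(plan) == "normal")
    if (length(candidates) == 0) break
    slot <- if (slot_choice == "earliest") candidates[1]
            else candidates[sample.int(length(candidates), 1L)]
    plan[slot] <- "reject"
  }
  plan
}

#' Play one full 20-trial condition
#'
#' Orchestrates the urn-model scheduler, the simulated user and the
#' fishing-game state machine for a single condition: plans the behaviors,
#' resolves each trial, applies the delivered feedback to the hooked fish,
#' reschedules unfired specials, and enforces the control cap after every
#' trial. A fish still hooked when trials run out escapes (counted as lost
#' by [summarize_condition()]).
#'
#' @inheritParams plan_condition
#' @param user a zero-argument function returning a logical per-trial
#'   attempt outcome, e.g. [bernoulli_user()] or [decoder_user()].
#' @param control_cap maximum fraction of positive-feedback trials allowed
#'   in helped conditions.
#' @param mode passed to [resolve_attempt()].
#' @param cap_trigger,cap_slot passed to [enforce_control_cap()].
#' @param cfg a [game_config()].
#' @return list of class `condition_run`: `trials` (one row per trial:
#'   behavior, attempt, feedback, change_label, special, fish id),
#'   `encounters` (one row per fish), `plan` (final behaviors), `urn`
#'   (delivered counts), and the condition parameters.
#' @examples
#' run <- run_condition("input_override", bernoulli_user(0.6), seed = 1)
#' table(run$trials$change_label)
#' @export
run_condition <- function(pam, user, n_trials = 20, help_target = 0.30,
                          control_cap = 0.70,
                          mode = c("experiment", "deployment"),
                          cap_trigger = c("above_target", "eager"),
                          cap_slot = c("random", "earliest"),
                          seed = NULL, cfg = game_config()) {
  pam <- match.arg(pam, PAM_KINDS)
  mode <- match.arg(mode)
  cap_trigger <- match.arg(cap_trigger)
  cap_slot <- match.arg(cap_slot)
  if (!is.null(seed)) set.seed(seed)

  plan <- plan_condition(pam, n_trials, help_target)
  fish <- spawn_fish(cfg)
  fish_id <- 1L
  encounters <- list()
  log <- vector("list", n_trials)
  delivered <- c(positive = 0L, negative = 0L, neutral = 0L, special = 0L)

  for (i in seq_len(n_trials)) {
    attempt <- isTRUE(user())
    out <- resolve_attempt(plan[i], pam, attempt, mode)
    if (out$defer_special) {
      plan[i] <- "normal"                  # the slot resolved as normal
      plan <- replan_after_failure(plan, i)
    }
    fish <- apply_feedback(fish, out$feedback, cfg)
    log[[i]] <- data.frame(
      trial = i, behavior = unclass(plan)[i], pam = pam, attempt = attempt,
      feedback = out$feedback, change_label = out$change_label,
      special = out$special_delivered, fish = fish_id,
      stringsAsFactors = FALSE)

    key <- if (out$feedback == "extra_positive") "positive" else out$feedback
    delivered[key] <- delivered[key] + 1L
    if (out$special_delivered) delivered["special"] <- delivered["special"] + 1L

    if (fish$state != "hooked") {
      encounters[[fish_id]] <- fish
      if (i < n_trials) {
        fish_id <- fish_id + 1L
        fish <- spawn_fish(cfg)
      } else fish <- NULL
    }
    plan <- enforce_control_cap(plan, delivered[["positive"]], i,
                                control_cap, cap_trigger, cap_slot)
  }
  if (!is.null(fish)) encounters[[fish_id]] <- fish   # end-of-condition fish

  enc_df <- data.frame(
    fish = seq_along(encounters),
    lane = vapply(encounters, `[[`, integer(1), "lane"),
    reel_progress = vapply(encounters, `[[`, integer(1), "reel_progress"),
    unreel_count = vapply(encounters, `[[`, integer(1), "unreel_count"),
    state = vapply(encounters, `[[`, character(1), "state"),
    stringsAsFactors = FALSE)

  structure(list(trials = do.call(rbind, log), encounters = enc_df,
                 plan = plan, urn = delivered, pam = pam,
                 n_trials = n_trials, help_target = help_target,
                 control_cap = control_cap, mode = mode),
            class = "condition_run")
}

#' @export
print.condition_run <- function(x, ...) {
  cat(sprintf("<condition_run> %s: %d trials, %d specials delivered, %s\n",
              x$pam, x$n_trials, x$urn[["special"]],
              paste(names(x$urn)[1:3], x$urn[1:3], collapse = ", ")))
  invisible(x)
}
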