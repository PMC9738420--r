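#' Reduce one condition's trial log to session-level variables
#'
#' Computes the per participant-condition explanatory variables used by the
#' analysis: the MI conversion rate (fraction of trials whose genuine MI
#' attempt succeeded), the positive-feedback rate (fraction of trials
#' delivering positive or extra-positive feedback, regardless of cause; an
#' extra-positive trial counts once), the PAM rate (fraction of trials in
#' which help was delivered), fish caught and lost, and reel/unreel event
#' counts (an extra-positive reel advances two steps and counts two reels).
#' A fish still hooked at trial exhaustion counts as lost.
#'
#' @param run a `condition_run` from [run_condition()], or a list with
#'   elements `trials` and `encounters` of the same shape.
#' @return one-row `data.frame` with columns `condition`,
#'   `mi_conversion_rate`, `positive_feedback`, `pam_rate`, `fish_caught`,
#'   `fish_lost`, `fish_reel`, `fish_unreel`, `n_trials`.
#' @export
summarize_condition <- function(run) {
  trials <- run$trials
  enc <- run$encounters
  if (is.null(trials) || nrow(trials) == 0) stop("empty trial log")
  n <- nrow(trials)
  pos <- trials$feedback %in% c("positive", "extra_positive")
  hooked_at_end <- sum(enc$state == "hooked")
  stopifnot(hooked_at_end <= 1)
  data.frame(
    condition = trials$pam[1],
    mi_conversion_rate = sum(trials$attempt) / n,
    positive_feedback = sum(pos) / n,
    pam_rate = sum(trials$special) / n,
    fish_caught = sum(enc$state == "caught"),
    fish_lost = sum(enc$state == "escaped") + hooked_at_end,
    fish_reel = sum(trials$feedback == "positive") +
      2L * sum(trials$feedback == "extra_positive"),
    fish_unreel = sum(trials$feedback == "negative"),
    n_trials = n,
    stringsAsFactors = FALSE)
}

#' Convert between normalized and ordinal Likert ratings
#'
#' The study tables print 7-point Likert ratings normalized from 1-7 to
#' 0-1; `recode_rating()` inverts that normalization back to integer
#' levels (`round(1 + 6 v)`, half away from zero), and
#' `normalize_rating()` maps levels back to the 0-1 grid. The analysis
#' always uses the ordinal levels; normalized values are display-only.
#'
#' @param normalized numeric in \[0, 1\].
#' @param level integer level in 1..7.
#' @return integer levels / numeric normalized values.
#' @examples
#' recode_rating(c(0, 0.17, 0.83, 1))
#' @export
recode_rating <- function(normalized) {
  if (any(normalized < 0 | normalized > 1, na.rm = TRUE)) {
    stop("normalized ratings must lie in [0, 1]")
  }
  as.integer(floor(1 + 6 * normalized + 0.5))
}

#' @rdname recode_rating
#' @export
normalize_rating <- function(level) {
  if (any(level < 1 | level > 7 | level != floor(level), na.rm = TRUE)) {
    stop("levels must be integers in 1..7")
  }
  (level - 1) / 6
}
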