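#' Fishing-game configuration
#'
#' Static rules of the fishing game: fish swim in one of three lanes
#' (depths); a hooked fish needs one to three successful reels to land
#' depending on its lane, and escapes after three unreels. Each trial has a
#' 2-s preparation phase and a 2-s input window, with MI initiated 2 s
#' after the last key press.
#'
#' @param n_lanes number of lanes (depths).
#' @param reels_to_catch reels needed to land a fish, one entry per lane.
#' @param unreels_to_escape unreels after which a hooked fish escapes.
#' @param prep_duration,input_window,post_key_delay phase durations, seconds.
#' @return object of class `game_config`.
#' @export
game_config <- function(n_lanes = 3, reels_to_catch = c(1, 2, 3),
                        unreels_to_escape = 3, prep_duration = 2,
                        input_window = 2, post_key_delay = 2) {
  stopifnot(n_lanes >= 1, length(reels_to_catch) == n_lanes,
            all(reels_to_catch >= 1), unreels_to_escape >= 1,
            prep_duration > 0, input_window > 0, post_key_delay > 0)
  structure(list(n_lanes = n_lanes, reels_to_catch = as.integer(reels_to_catch),
                 unreels_to_escape = unreels_to_escape,
                 prep_duration = prep_duration, input_window = input_window,
                 post_key_delay = post_key_delay),
            class = "game_config")
}

#' Spawn a fish in a uniformly random lane
#'
#' Uses the current RNG stream; the simulated player always hooks the
#' spawned fish (hook movement is abstracted away).
#'
#' @param cfg a [game_config()].
#' @return object of class `fish_encounter`: `lane`, `reel_progress`,
#'   `unreel_count`, `state` (`"hooked"`, `"caught"` or `"escaped"`).
#' @export
spawn_fish <- function(cfg = game_config()) {
  structure(list(lane = sample.int(cfg$n_lanes, 1L),
                 reel_progress = 0L, unreel_count = 0L, state = "hooked"),
            class = "fish_encounter")
}

#' Apply one trial's feedback to a hooked fish
#'
#' Positive feedback reels the fish up one lane-step, extra positive
#' (augmented success) two steps, neutral leaves it in place, and negative
#' unreels it once. State transitions are applied after the increment: the
#' fish is caught once `reel_progress` reaches the lane's requirement
#' (overshoot capped) and escapes at the third unreel.
#'
#' @param enc a hooked `fish_encounter`.
#' @param kind `"positive"`, `"extra_positive"`, `"neutral"` or `"negative"`.
#' @param cfg a [game_config()].
#' @return the updated `fish_encounter`.
#' @export
apply_feedback <- function(enc, kind, cfg = game_config()) {
  stopifnot(inherits(enc, "fish_encounter"))
  if (enc$state != "hooked") {
    stop("feedback applied to a resolved (caught/escaped) encounter")
  }
  kind <- match.arg(kind, c("positive", "extra_positive", "neutral", "negative"))
  need <- cfg$reels_to_catch[enc$lane]
  step <- switch(kind, positive = 1L, extra_positive = 2L, neutral = 0L,
                 negative = 0L)
  enc$reel_progress <- min(enc$reel_progress + step, need)
  if (kind == "negative") enc$unreel_count <- enc$unreel_count + 1L
  if (enc$reel_progress >= need) {
    enc$state <- "caught"
  } else if (enc$unreel_count >= cfg$unreels_to_escape) {
    enc$state <- "escaped"
  }
  enc
}

#' Timeline of a single trial attempt
#'
#' A trial consists of a preparation phase followed by the input window;
#' the window closes at the detection latency (success) or at its full
#' length (failure).
#'
#' @param cfg a [game_config()].
#' @param detection a [detect_mi()] result (`detected`, `latency`).
#' @return list with `success`, and the phase timing `prep_start`,
#'   `window_open`, `window_close` (seconds from trial start).
#' @export
run_trial_timeline <- function(cfg, detection) {
  success <- isTRUE(detection$detected)
  close_at <- if (success) min(detection$latency, cfg$input_window)
              else cfg$input_window
  list(success = success,
       prep_start = 0, window_open = cfg$prep_duration,
       window_close = cfg$prep_duration + close_at)
}
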