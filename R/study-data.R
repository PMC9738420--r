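#' Load the packaged per-participant study table
#'
#' Reads the transcribed per participant-condition session table (18
#' participants x 4 conditions, one missing cell) together with the
#' participant demographics, validates it, and derives the analysis
#' columns: ordinal 1-7 rating levels via [recode_rating()], proportions
#' from the printed whole percentages, and a condition factor with the
#' reference (`normal`) condition as first level.
#'
#' Validation enforces the table's structural invariants: every
#' participant-condition cell present (complete or flagged missing),
#' normalized ratings on the 1/6 grid of a 7-point scale, and feedback /
#' conversion percentages that are multiples of 5 (each condition has 20
#' trials). Known transcription quirks that are *printed* in the source
#' table -- participant 1's all-zero fish counts despite high positive
#' feedback -- are kept and reported via a message, not altered.
#'
#' @param path,participants_path optional overrides of the packaged
#'   delimited files.
#' @return `data.frame` of class `study_table`, one row per
#'   participant-condition (72 rows; 71 complete), with demographics
#'   merged in and attribute `provenance`.
#' @examples
#' tab <- load_study_table()
#' nrow(complete_sessions(tab))
#' @export
load_study_table <- function(path = NULL, participants_path = NULL) {
  path <- path %||%
    system.file("extdata", "study_sessions.tsv", package = "pamgame")
  participants_path <- participants_path %||%
    system.file("extdata", "study_participants.tsv", package = "pamgame")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  demo <- utils::read.delim(participants_path, stringsAsFactors = FALSE)

  required <- c("participant", "condition", "perceived_control",
                "frustration", "mi_conversion_pct", "positive_feedback_pct",
                "fish_caught", "fish_lost")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("session table lacks columns: ", paste(missing_cols, collapse = ", "))
  }

  # normalize unicode minus and stray percent signs, then coerce
  for (col in c("mi_conversion_pct", "positive_feedback_pct")) {
    if (is.character(tab[[col]])) {
      tab[[col]] <- as.numeric(gsub("[%−]", "", tab[[col]]))
    }
  }

  problems <- character()
  cell <- function(i, what) sprintf("P%d/%s: %s", tab$participant[i],
                                    tab$condition[i], what)
  for (col in c("perceived_control", "frustration")) {
    v <- tab[[col]]
    off <- which(!is.na(v) & abs(6 * v - round(6 * v)) > 0.05)
    problems <- c(problems,
                  vapply(off, cell, "", what = paste(col, "off the 1/6 grid")))
  }
  for (col in c("mi_conversion_pct", "positive_feedback_pct")) {
    v <- tab[[col]]
    off <- which(!is.na(v) & (v %% 5 != 0 | v < 0 | v > 100))
    problems <- c(problems,
                  vapply(off, cell, "", what = paste(col, "not a multiple of 5%")))
  }
  if (length(problems)) {
    stop("invalid study table cells:\n  ", paste(problems, collapse = "\n  "))
  }
  if (nrow(tab) != nrow(unique(tab[c("participant", "condition")]))) {
    stop("duplicated participant-condition rows")
  }

  ref <- tab$condition == "normal"
  if (any(tab$positive_feedback_pct[ref] != tab$mi_conversion_pct[ref],
          na.rm = TRUE)) {
    stop("reference condition must have positive feedback == MI conversion")
  }

  zero_fish <- stats::aggregate(fish_caught + fish_lost ~ participant,
                                data = tab, sum)
  odd <- zero_fish$participant[zero_fish[[2]] == 0]
  if (length(odd)) {
    message("note: participant(s) ", paste(odd, collapse = ", "),
            " have all-zero fish counts as printed in the source table")
  }

  tab <- merge(demo, tab, by = "participant", sort = FALSE)
  tab$condition <- factor(tab$condition, levels = PAM_KINDS)
  tab$perceived_control_level <- recode_rating(tab$perceived_control)
  tab$frustration_level <- recode_rating(tab$frustration)
  tab$mi_conversion_rate <- tab$mi_conversion_pct / 100
  tab$positive_feedback <- tab$positive_feedback_pct / 100
  tab <- tab[order(tab$participant, tab$condition), ]
  rownames(tab) <- NULL
  structure(tab, provenance = "packaged study table",
            class = c("study_table", "data.frame"))
}

#' @rdname load_study_table
#' @param tab a `study_table`.
#' @return `complete_sessions()`: the rows with no missing analysis cells.
#' @export
complete_sessions <- function(tab) {
  keep <- stats::complete.cases(
    tab[c("perceived_control", "frustration", "mi_conversion_pct",
          "positive_feedback_pct", "fish_caught", "fish_lost")])
  out <- tab[keep, ]
  rownames(out) <- NULL
  out
}

#' Write a study table back to delimited text
#'
#' Inverse of [load_study_table()] for the session columns; a written table
#' reloads to an identical `study_table` (round-trip).
#'
#' @param tab a `study_table`.
#' @param path output path for the session table.
#' @export
write_study_table <- function(tab, path) {
  cols <- c("participant", "condition", "perceived_control", "frustration",
            "mi_conversion_pct", "positive_feedback_pct",
            "fish_caught", "fish_lost")
  out <- as.data.frame(tab)[cols]
  out$condition <- as.character(out$condition)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a study-table-shaped cohort through the full pipeline
#'
#' Replays the whole simulator end to end: for every participant and
#' condition, the urn-model scheduler and game engine are driven by a
#' Bernoulli attempt model at the participant's MI conversion rate (or by
#' a full decoder-based simulated user), and the resulting trial logs are
#' reduced with [summarize_condition()]. Ratings are left missing -- the
#' package has no generative model of human ratings.
#'
#' @param conversion_rates named or unnamed vector of per-participant
#'   trial success probabilities; defaults to the packaged reference-
#'   condition MI conversion rates (range 0.05-1 in the study, mean 0.54).
#' @param seed integer seed for the whole cohort.
#' @param conditions conditions to play per participant.
#' @param users optional list of zero-argument attempt functions, one per
#'   participant, overriding the Bernoulli model (e.g. [decoder_user()]).
#' @inheritParams run_condition
#' @return `data.frame`, one row per participant-condition, with the
#'   [summarize_condition()] variables plus `participant` and `pct`
#'   convenience columns matching the packaged table's schema.
#' @export
simulate_cohort <- function(conversion_rates = NULL, seed = NULL,
                            conditions = PAM_KINDS,
                            users = NULL, n_trials = 20, help_target = 0.30,
                            control_cap = 0.70, mode = "experiment",
                            cap_trigger = "above_target") {
  if (is.null(conversion_rates)) {
    tab <- load_study_table()
    ref <- tab[tab$condition == "normal", ]
    conversion_rates <- stats::setNames(ref$mi_conversion_rate,
                                        ref$participant)
  }
  stopifnot(all(conversion_rates >= 0 & conversion_rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(conversion_rates) %||% seq_along(conversion_rates)

  rows <- list()
  for (p in seq_along(conversion_rates)) {
    user <- if (!is.null(users)) users[[p]]
            else bernoulli_user(conversion_rates[p])
    for (cond in conditions) {
      run <- run_condition(cond, user, n_trials = n_trials,
                           help_target = help_target,
                           control_cap = control_cap, mode = mode,
                           cap_trigger = cap_trigger)
      s <- summarize_condition(run)
      s$participant <- ids[p]
      rows[[length(rows) + 1L]] <- s
    }
  }
  out <- do.call(rbind, rows)
  out$mi_conversion_pct <- 100 * out$mi_conversion_rate
  out$positive_feedback_pct <- 100 * out$positive_feedback
  out$perceived_control <- NA_real_
  out$frustration <- NA_real_
  out[c("participant", "condition", "perceived_control", "frustration",
        "mi_conversion_pct", "positive_feedback_pct", "fish_caught",
        "fish_lost", "fish_reel", "fish_unreel", "pam_rate",
        "mi_conversion_rate", "positive_feedback", "n_trials")]
}
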