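#' Standard montage used throughout the package
#'
#' Seven-channel 10-20 montage over frontal, central and parietal sites.
#' @keywords internal
MONTAGE <- c("F3", "F4", "C3", "Cz", "C4", "P3", "P4")

# channels carrying the sensorimotor rhythm that desynchronizes during MI
ERD_CHANNELS <- c("C3", "Cz")

#' Generate synthetic calibration epochs with event-related desynchronization
#'
#' Emulates a two-class motor-imagery calibration recording: each epoch is
#' 4 s of 7-channel EEG at 250 Hz, built from broadband noise plus
#' band-limited mu (8-12 Hz) and beta (13-30 Hz) rhythms. During motor
#' imagery (MI) the rhythm power over the motor channels C3 and Cz is
#' attenuated by the factor `1 - erd_depth`, mimicking event-related
#' desynchronization; idle epochs keep full rhythm power. With
#' `erd_depth = 0` the two classes are statistically identical.
#'
#' @param n_mi,n_idle number of MI and idle epochs (both positive).
#' @param erd_depth fraction in \[0, 1\]: proportion of mu/beta band power
#'   suppressed on C3/Cz during MI. 0 gives indistinguishable classes.
#' @param noise_sd standard deviation of the broadband noise floor, in uV.
#' @param seed optional integer seed; fixed seed gives identical epochs.
#' @param duration epoch length in seconds.
#' @param rate sampling rate in Hz.
#' @param mu_sd,beta_sd standard deviation of the mu and beta rhythm
#'   components, in uV, before any ERD attenuation.
#' @return An object of class `epoch_set`: list with `samples`
#'   (array epoch x channel x time, uV), `labels` (factor `mi`/`idle`),
#'   `rate`, and `channels`.
#' @examples
#' ep <- synthetic_mi_epochs(10, 10, erd_depth = 0.8, seed = 1)
#' dim(ep$samples)
#' @export
synthetic_mi_epochs <- function(n_mi = 30, n_idle = 30, erd_depth = 0.5,
                                noise_sd = 1, seed = NULL,
                                duration = 4, rate = 250,
                                mu_sd = 2, beta_sd = 1) {
  if (n_mi <= 0 || n_idle <= 0) stop("epoch counts must be positive")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  n_samp <- round(duration * rate)
  n_chan <- length(MONTAGE)
  n_ep <- n_mi + n_idle
  labels <- factor(rep(c("mi", "idle"), c(n_mi, n_idle)),
                   levels = c("mi", "idle"))

  # rhythm components: band-limited gaussian noise, regenerated per epoch
  # and channel so phases are independent across the montage
  mu_filt <- signal::butter(4, c(8, 12) / (rate / 2), type = "pass")
  beta_filt <- signal::butter(4, c(13, 30) / (rate / 2), type = "pass")
  keep_power <- sqrt(1 - erd_depth)
  erd_idx <- match(ERD_CHANNELS, MONTAGE)

  band_noise <- function(filt, target_sd) {
    x <- signal::filtfilt(filt, stats::rnorm(n_samp + 2 * rate))
    x <- x[(rate + 1):(rate + n_samp)]        # drop filter edges
    x * target_sd / stats::sd(x)
  }

  samples <- array(0, dim = c(n_ep, n_chan, n_samp),
                   dimnames = list(NULL, MONTAGE, NULL))
  for (e in seq_len(n_ep)) {
    # mild epoch-to-epoch amplitude variability of the background rhythm
    amp <- exp(stats::rnorm(1, 0, 0.1))
    for (c in seq_len(n_chan)) {
      rhythm <- amp * (band_noise(mu_filt, mu_sd) + band_noise(beta_filt, beta_sd))
      if (labels[e] == "mi" && c %in% erd_idx) rhythm <- rhythm * keep_power
      samples[e, c, ] <- rhythm + stats::rnorm(n_samp, 0, noise_sd)
    }
  }

  structure(list(samples = samples, labels = labels,
                 rate = rate, channels = MONTAGE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<epoch_set> %d epochs (%s), %d channels, %d samples @ %g Hz\n",
              d[1], paste(sprintf("%s: %d", levels(x$labels),
                                  tabulate(x$labels)), collapse = ", "),
              d[2], d[3], x$rate))
  invisible(x)
}

#' Continuous synthetic signal for one game trial window
#'
#' Produces a multichannel signal covering an optional lead-in (preroll)
#' followed by the trial's input window. `kind = "mi"` applies the ERD
#' attenuation on C3/Cz for the whole window; `kind = "idle"` does not.
#' The preroll is always idle-like.
#'
#' @inheritParams synthetic_mi_epochs
#' @param kind `"mi"` or `"idle"`: what the simulated user does in the window.
#' @param window window length in seconds.
#' @param preroll idle lead-in in seconds (so a sliding analysis buffer has
#'   history at the first decision).
#' @return channel x time matrix with attributes `rate` and `preroll`.
#' @export
synthetic_window_signal <- function(kind = c("mi", "idle"), erd_depth = 0.5,
                                    noise_sd = 1, window = 2, preroll = 1,
                                    rate = 250, mu_sd = 2, beta_sd = 1) {
  kind <- match.arg(kind)
  total <- preroll + window
  ep <- synthetic_mi_epochs(1, 1, erd_depth = erd_depth, noise_sd = noise_sd,
                            duration = total, rate = rate,
                            mu_sd = mu_sd, beta_sd = beta_sd)
  use <- if (kind == "mi") 1L else 2L
  sig <- ep$samples[use, , ]
  if (preroll > 0) {
    # lead-in taken from the idle epoch regardless of window kind
    pre_n <- round(preroll * rate)
    sig[, seq_len(pre_n)] <- ep$samples[2L, , seq_len(pre_n)]
  }
  rownames(sig) <- MONTAGE
  structure(sig, rate = rate, preroll = preroll)
}
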