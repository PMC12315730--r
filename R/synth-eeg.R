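#' Configuration for the synthetic EEG generator
#'
#' Describes the signal model the analysis chain assumes: a mu-band oscillator
#' over a C3-like target channel (attenuated during motor imagery by
#' `erd_depth`), an optional beta harmonic at twice the mu frequency, spatially
#' attenuated copies on six neighbouring channels, independent 1/f background
#' noise per channel, one shared common-mode 1/f component, and 50 Hz mains
#' contamination.
#'
#' @param n_channels channel count (default 12: target + 6 neighbours + 5
#'   mu-silent background channels). The background channels emulate the rest
#'   of a dense whole-head montage: they carry the same background noise,
#'   common mode, and mains component but no mu signal, so the common average
#'   reference subtracts only a small fraction of the target's mu amplitude —
#'   as it does on a dense net, where the scalp-wide average contains little
#'   of the focal rhythm.
#' @param srate sampling rate in Hz (default 1000).
#' @param target_channel label of the mu-carrying channel (default `"C3"`).
#' @param neighbor_channels labels of the six surrounding channels.
#' @param mu_freq mu oscillator frequency in Hz (default 11).
#' @param mu_amp_rest mu amplitude at rest in uV (default 20).
#' @param erd_depth fractional mu *power* attenuation during imagery, in
#'   `[0, 1]`: imagery-epoch mu-band power equals `(1 - erd_depth)` times
#'   rest-epoch power in expectation.
#' @param beta_coupling amplitude of the beta harmonic (at `2 * mu_freq`) as a
#'   fraction of the mu amplitude (default 0.3); the harmonic follows the same
#'   imagery attenuation.
#' @param neighbor_atten fraction of the mu signal mixed into each neighbour
#'   channel (default 0.3), keeping the target focal but the Laplacian
#'   non-degenerate.
#' @param noise_exponent 1/f slope of the per-channel background (default 1;
#'   0 gives white noise).
#' @param noise_level per-channel background PSD at 10 Hz in uV^2/Hz
#'   (default 1; 0 disables).
#' @param common_mode_level PSD at 10 Hz of the shared common-mode component
#'   (default 1; cancelled by both the Laplacian and the common average
#'   reference).
#' @param line_noise_amp 50 Hz mains amplitude in uV, identical on all
#'   channels (default 2).
#' @param amp_jitter_sd per-trial multiplicative jitter (sd of a Gaussian
#'   factor with mean 1) of the mu amplitude. Inter-trial variability of the
#'   rhythm is not characterized in the literature this model follows, so it
#'   is exposed as a free parameter rather than asserted; the default 0
#'   realizes the plain amplitude-modulated-oscillator model, and nonzero
#'   values probe estimator robustness to amplitude non-stationarity.
#' @param seed integer seed or `NULL` to use the current RNG state.
#' @return A validated `eeg_gen_config` list.
#' @export
eeg_gen_config <- function(n_channels = 12, srate = 1000,
                           target_channel = "C3",
                           neighbor_channels = c("FC3", "FC5", "C1", "C5",
                                                 "CP3", "CP5"),
                           mu_freq = 11, mu_amp_rest = 20, erd_depth = 0.5,
                           beta_coupling = 0.3, neighbor_atten = 0.3,
                           noise_exponent = 1, noise_level = 1,
                           common_mode_level = 1, line_noise_amp = 2,
                           amp_jitter_sd = 0, seed = NULL) {
  if (erd_depth < 0 || erd_depth > 1)
    stop("`erd_depth` must lie in [0, 1]")
  if (length(neighbor_channels) != 6L)
    stop("exactly six neighbour channels are required")
  if (target_channel %in% neighbor_channels)
    stop("neighbour set must exclude the target channel")
  if (anyDuplicated(neighbor_channels))
    stop("neighbour channels must be distinct")
  if (n_channels < 7L)
    stop("`n_channels` must be at least 7 (target + 6 neighbours)")
  if (mu_freq <= 0 || mu_amp_rest < 0 || noise_level < 0 ||
      common_mode_level < 0 || line_noise_amp < 0 || amp_jitter_sd < 0)
    stop("amplitudes and levels must be non-negative")
  structure(as.list(environment()), class = "eeg_gen_config")
}

# Set the RNG from an integer seed when one is given; generators record the
# seed in output metadata either way.
use_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}

# Spectrally shaped Gaussian noise: one-sided PSD level * (10/f)^exponent
# uV^2/Hz, flattened below 0.5 Hz to keep the variance finite. Drawn directly
# in the frequency domain (hermitian complex-Gaussian spectrum, one inverse
# FFT).
shaped_noise <- function(n, srate, level, exponent) {
  if (level <= 0) return(numeric(n))
  nf <- n %/% 2
  f <- seq_len(nf) * srate / n
  g <- sqrt(level * (10 / pmax(f, 0.5))^exponent * srate / 2)
  # positive-frequency spectrum; each complex bin has total variance n
  Z <- complex(real = stats::rnorm(nf, sd = sqrt(n / 2)),
               imaginary = stats::rnorm(nf, sd = sqrt(n / 2))) * g
  X <- complex(length.out = n)
  X[2:(nf + 1)] <- Z
  X[n:(n - nf + 2)] <- Conj(Z[seq_len(nf - 1)])
  if (n %% 2 == 0) X[nf + 1] <- sqrt(2) * Re(Z[nf])  # real Nyquist bin
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Mu amplitude envelope over the recording: 1 at rest / inter-trial, linear
# ramp to sqrt(1 - erd_depth) across the ready epoch, held through imagery,
# smooth recovery to the rest level over 0.5 s after imagery end (abrupt
# amplitude steps would inject broadband clicks no physiological rhythm has).
erd_envelope <- function(tt, schedule, erd_depth, recover_dur = 0.5) {
  env <- rep(1, length(tt))
  target <- sqrt(1 - erd_depth)
  for (i in seq_len(nrow(schedule))) {
    rdy <- schedule$ready_onset[i]; img <- schedule$imagery_onset[i]
    end <- schedule$imagery_end[i]
    ramp <- tt >= rdy & tt < img
    env[ramp] <- 1 + (target - 1) * (tt[ramp] - rdy) / (img - rdy)
    env[tt >= img & tt < end] <- target
    rec <- tt >= end & tt < end + recover_dur
    env[rec] <- target + (1 - target) * (tt[rec] - end) / recover_dur
  }
  env
}

#' Generate synthetic EEG for a block of trials
#'
#' Realizes the model described in [eeg_gen_config()] over a trial schedule.
#' The mu oscillator carries an independent random phase and amplitude jitter
#' per trial; its envelope ramps down linearly across the 1-s ready epoch and
#' holds the attenuated level through imagery, so the imagery/rest mu-band
#' power ratio equals `1 - erd_depth` in expectation.
#'
#' @param cfg an [eeg_gen_config()].
#' @param schedule a [trial_schedule()].
#' @param tail_dur extra seconds of rest-state signal appended after the last
#'   imagery epoch (default 1, so the offline segmentation window fits).
#' @return A [recording()]; `meta$ground_truth` stores the configuration,
#'   schedule, and the injected ERD depth.
#' @export
#' @examples
#' cfg <- eeg_gen_config(erd_depth = 0.4, seed = 1)
#' rec <- generate_eeg(cfg, trial_schedule(2, iti = 0))
generate_eeg <- function(cfg, schedule, tail_dur = 1) {
  stopifnot(inherits(cfg, "eeg_gen_config"))
  validate_schedule(schedule)
  use_seed(cfg$seed)
  srate <- cfg$srate
  duration <- schedule_duration(schedule) + tail_dur
  n <- round(duration * srate)
  tt <- (seq_len(n) - 1) / srate

  # per-trial phase and amplitude jitter; trial i owns [rest_onset_i, next)
  ntr <- nrow(schedule)
  phase_mu <- stats::runif(ntr, 0, 2 * pi)
  phase_beta <- stats::runif(ntr, 0, 2 * pi)
  jitter <- pmax(1 + stats::rnorm(ntr, 0, cfg$amp_jitter_sd), 0.1)
  bounds <- c(schedule$rest_onset, Inf)
  trial_of <- findInterval(tt, bounds, rightmost.closed = FALSE)
  trial_of[trial_of < 1L] <- 1L

  # raised-cosine crossfade (200 ms) between successive trials' random
  # phases: per-trial phase without broadband discontinuities
  prev_of <- pmax(trial_of - 1L, 1L)
  xf <- pmin((tt - schedule$rest_onset[trial_of]) / 0.2, 1)
  xf[trial_of == 1L] <- 1
  w <- 0.5 - 0.5 * cos(pi * pmax(xf, 0))
  blend <- function(freq, phases) {
    (1 - w) * sin(2 * pi * freq * tt + phases[prev_of]) +
      w * sin(2 * pi * freq * tt + phases[trial_of])
  }
  jit <- (1 - w) * jitter[prev_of] + w * jitter[trial_of]
  env <- erd_envelope(tt, schedule, cfg$erd_depth) * jit
  mu <- cfg$mu_amp_rest * env * blend(cfg$mu_freq, phase_mu)
  if (cfg$beta_coupling > 0) {
    mu <- mu + cfg$beta_coupling * cfg$mu_amp_rest * env *
      blend(2 * cfg$mu_freq, phase_beta)
  }

  labels <- c(cfg$target_channel, cfg$neighbor_channels)
  if (cfg$n_channels > 7L)
    labels <- c(labels, paste0("E", seq_len(cfg$n_channels - 7L)))
  mix <- c(1, rep(cfg$neighbor_atten, 6), rep(0, cfg$n_channels - 7L))

  common <- shaped_noise(n, srate, cfg$common_mode_level, cfg$noise_exponent)
  line <- if (cfg$line_noise_amp > 0) {
    cfg$line_noise_amp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
  } else 0

  dat <- matrix(0, nrow = cfg$n_channels, ncol = n)
  for (ch in seq_len(cfg$n_channels)) {
    dat[ch, ] <- mix[ch] * mu + common + line +
      shaped_noise(n, srate, cfg$noise_level, cfg$noise_exponent)
  }

  truth <- list(erd_depth = cfg$erd_depth, mu_freq = cfg$mu_freq,
                mu_amp_rest = cfg$mu_amp_rest, seed = cfg$seed,
                trial_jitter = jitter)
  recording(dat, srate, labels,
            meta = list(ground_truth = truth, config = cfg,
                        schedule = as.data.frame(schedule)))
}

#' Write the generator's ground truth next to a recording file
#'
#' @param rec a generated [recording()].
#' @param path JSON path (conventionally `<recording>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(rec, path) {
  truth <- rec$meta$ground_truth
  if (is.null(truth)) stop("recording carries no ground truth")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
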