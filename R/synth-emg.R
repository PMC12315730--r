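#' Configuration for the synthetic EMG trial generator
#'
#' Models a surface EMG trace around a visual Go cue: Gaussian baseline noise
#' of standard deviation `baseline_sd`, and a voluntary burst — Gaussian noise
#' whose standard deviation rises rapidly to `burst_amp` — starting exactly
#' `rt_true` seconds after the cue. `burst_amp / baseline_sd` is the
#' controllable signal-to-noise ratio of the burst. Optionally a shorter burst
#' is inserted before the cue to emulate anticipatory muscle potentiation.
#'
#' @param rt_true true reaction time in seconds (burst onset minus go cue).
#' @param burst_amp burst standard deviation in uV (default 80).
#' @param baseline_sd baseline standard deviation in uV (default 10).
#' @param go_time Go-cue time in seconds from trace start (default 1).
#' @param pre_cue_burst insert an anticipatory burst 0.5 s before the cue
#'   (default `FALSE`).
#' @param burst_dur burst duration in seconds (default 0.3).
#' @param rise_time 0-to-full rise time of the burst envelope in seconds
#'   (default 0.002, near-step onset).
#' @param srate sampling rate in Hz (default 10000).
#' @param seed integer seed or `NULL`.
#' @return A validated `emg_gen_config` list.
#' @export
emg_gen_config <- function(rt_true, burst_amp = 80, baseline_sd = 10,
                           go_time = 1, pre_cue_burst = FALSE,
                           burst_dur = 0.3, rise_time = 0.002,
                           srate = 10000, seed = NULL) {
  if (rt_true < 0) stop("`rt_true` must be non-negative")
  if (baseline_sd <= 0) stop("`baseline_sd` must be positive")
  if (burst_amp < 0) stop("`burst_amp` must be non-negative")
  structure(as.list(environment()), class = "emg_gen_config")
}

#' Draw Go-cue times for a reaction-time session
#'
#' Cues are generated every `base` plus/minus `jitter` seconds (uniform), the
#' pacing of the simple reaction-time task.
#'
#' @param n number of cues.
#' @param base mean inter-cue interval in seconds (default 6).
#' @param jitter half-range of the uniform jitter in seconds (default 1).
#' @param first time of the first cue (default `base`).
#' @param seed integer seed or `NULL`.
#' @return Numeric vector of cue times in seconds.
#' @export
draw_go_times <- function(n, base = 6, jitter = 1, first = base, seed = NULL) {
  use_seed(seed)
  if (n < 1) stop("`n` must be at least 1")
  first + c(0, cumsum(stats::runif(n - 1, base - jitter, base + jitter)))
}

burst_envelope <- function(tt, onset, dur, rise) {
  env <- numeric(length(tt))
  up <- tt >= onset & tt < onset + rise
  env[up] <- (tt[up] - onset) / rise
  env[tt >= onset + rise & tt < onset + dur] <- 1
  fall <- tt >= onset + dur & tt < onset + dur + 0.05
  env[fall] <- 1 - (tt[fall] - onset - dur) / 0.05
  env
}

#' Generate one synthetic EMG reaction-time trial
#'
#' @param cfg an [emg_gen_config()].
#' @param duration trace length in seconds; must exceed
#'   `go_time + rt_true` (default covers the burst with 0.5 s to spare).
#' @return A single-channel [recording()] (label `"EDC"`);
#'   `meta$ground_truth` records the true onset `go_time + rt_true` and the
#'   pre-cue-burst flag.
#' @export
#' @examples
#' cfg <- emg_gen_config(rt_true = 0.15, seed = 1)
#' trial <- generate_emg_trial(cfg)
#' trial$meta$ground_truth$onset_true
generate_emg_trial <- function(cfg,
                               duration = cfg$go_time + cfg$rt_true +
                                 cfg$burst_dur + 0.5) {
  stopifnot(inherits(cfg, "emg_gen_config"))
  if (cfg$go_time + cfg$rt_true >= duration)
    stop("`duration` must exceed go_time + rt_true")
  use_seed(cfg$seed)
  n <- round(duration * cfg$srate)
  tt <- (seq_len(n) - 1) / cfg$srate
  onset <- cfg$go_time + cfg$rt_true
  sd_prof <- rep(cfg$baseline_sd, n)
  env <- burst_envelope(tt, onset, cfg$burst_dur, cfg$rise_time)
  sd_prof <- pmax(sd_prof, env * cfg$burst_amp)
  if (cfg$pre_cue_burst) {
    pre_onset <- max(cfg$go_time - 0.5, 0)
    pre_env <- burst_envelope(tt, pre_onset, 0.15, cfg$rise_time)
    sd_prof <- pmax(sd_prof, pre_env * cfg$burst_amp)
  }
  x <- stats::rnorm(n) * sd_prof
  truth <- list(onset_true = onset, go_time = cfg$go_time,
                rt_true = cfg$rt_true, pre_cue_burst = cfg$pre_cue_burst,
                seed = cfg$seed)
  recording(x, cfg$srate, "EDC",
            meta = list(ground_truth = truth, config = cfg))
}
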