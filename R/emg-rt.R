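#' EMG onset-detection configuration
#'
#' Parameters of the burst-onset rule: the detection threshold is
#' `threshold_factor` times the standard deviation of the band-passed,
#' rectified signal over a baseline window immediately preceding the Go cue;
#' the onset is the first post-cue time where the rectified envelope exceeds
#' the threshold and stays above it for `sustain` seconds.
#'
#' @param threshold_factor multiplier on the baseline SD (default 4).
#' @param baseline_window length of the pre-cue baseline window in seconds
#'   (default 0.5).
#' @param sustain minimum sustained exceedance in seconds (default 0.010);
#'   set to 0 to recover the literal first-crossing rule.
#' @param smooth causal moving-average window applied to the rectified signal
#'   before thresholding, in seconds (default 0.005; 0 disables smoothing).
#' @param bandpass acquisition band-pass edges in Hz (default `c(10, 500)`).
#' @param bp_order band-pass order (default 2, the acquisition setting).
#' @param inspect_window pre-cue inspection span for anticipatory-burst
#'   rejection, in seconds (default 1).
#' @return An `rt_config` list.
#' @export
rt_config <- function(threshold_factor = 4, baseline_window = 0.5,
                      sustain = 0.010, smooth = 0.005,
                      bandpass = c(10, 500), bp_order = 2,
                      inspect_window = 1) {
  if (threshold_factor < 0) stop("`threshold_factor` must be non-negative")
  structure(as.list(environment()), class = "rt_config")
}

emg_envelope <- function(rec, cfg) {
  filt <- causal_filter(rec, cfg$bandpass[1], cfg$bandpass[2], cfg$bp_order,
                        notch_freq = NULL)
  rect <- abs(filt$data[1L, ])
  k <- round(cfg$smooth * rec$srate)
  env <- if (k > 1) {
    c(cumsum(rect[1:k]) / seq_len(k),
      (cumsum(rect)[-seq_len(k)] -
         cumsum(rect)[seq_len(length(rect) - k)]) / k)
  } else rect
  list(rect = rect, env = env)
}

first_sustained <- function(above, sus_n) {
  if (!any(above)) return(NA_integer_)
  if (sus_n <= 1L) return(which(above)[1L])
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= sus_n)
  if (!length(ok)) return(NA_integer_)
  ends[ok[1L]] - r$lengths[ok[1L]] + 1L
}

#' Detect EMG burst onset after a Go cue
#'
#' Implements the 4-SD rule: the threshold is `threshold_factor` times the SD
#' of the rectified baseline (the `baseline_window` seconds before the cue,
#' after the 10–500 Hz acquisition band-pass); the onset is the first post-cue
#' sample whose rectified envelope exceeds the threshold and remains above it
#' for at least `sustain` seconds. Detection can only lag a true threshold
#' crossing, never lead it.
#'
#' @param trace single-channel EMG [recording()].
#' @param go_time Go-cue time in seconds.
#' @param cfg an [rt_config()].
#' @return Onset time in seconds, or `NA` if the threshold is never sustained.
#' @export
#' @examples
#' trial <- generate_emg_trial(emg_gen_config(rt_true = 0.15, seed = 1))
#' detect_onset(trial, go_time = 1)
detect_onset <- function(trace, go_time, cfg = rt_config()) {
  srate <- trace$srate
  tt <- sample_times(trace)
  b0 <- go_time - cfg$baseline_window
  if (b0 < tt[1] - 1e-9)
    stop("baseline window [", b0, ", ", go_time, "] s precedes the trace")
  e <- emg_envelope(trace, cfg)
  base <- e$rect[tt >= b0 & tt < go_time]
  thr <- cfg$threshold_factor * stats::sd(base)
  post <- which(tt >= go_time)
  if (!length(post)) stop("trace ends before the Go cue")
  idx <- first_sustained(e$env[post] > thr, round(cfg$sustain * srate))
  if (is.na(idx)) return(NA_real_)
  tt[post[idx]]
}

#' Flag anticipatory EMG potentiation before the Go cue
#'
#' Rejects trials in which the muscle was already active before the cue: the
#' rectified envelope within the pre-cue inspection window is compared against
#' the same 4-SD threshold, computed on an earlier reference segment (the
#' first `baseline_window` seconds of the trace).
#'
#' @inheritParams detect_onset
#' @return `TRUE` if pre-cue activity exceeds the threshold.
#' @export
reject_precue <- function(trace, go_time, cfg = rt_config()) {
  tt <- sample_times(trace)
  e <- emg_envelope(trace, cfg)
  ref <- e$rect[tt < tt[1] + cfg$baseline_window]
  if (!length(ref)) stop("trace shorter than the reference segment")
  thr <- cfg$threshold_factor * stats::sd(ref)
  insp <- tt >= max(tt[1] + cfg$baseline_window, go_time - cfg$inspect_window) &
    tt < go_time
  any(e$env[insp] > thr)
}

#' Score one reaction-time trial
#'
#' Combines pre-cue rejection and onset detection into the per-trial record.
#'
#' @inheritParams detect_onset
#' @param trial trial identifier copied into the output row.
#' @return One-row data.frame: `trial`, `go_time`, `onset_time`, `rt`,
#'   `rejected`, `reason`.
#' @export
rt_trial <- function(trace, go_time, cfg = rt_config(), trial = NA) {
  pre <- reject_precue(trace, go_time, cfg)
  onset <- if (pre) NA_real_ else detect_onset(trace, go_time, cfg)
  rejected <- pre || is.na(onset)
  data.frame(trial = trial, go_time = go_time, onset_time = onset,
             rt = if (rejected) NA_real_ else onset - go_time,
             rejected = rejected,
             reason = if (pre) "pre-cue EMG potentiation"
                      else if (is.na(onset)) "no burst detected" else "")
}

#' Session reaction-time summary
#'
#' @param trials data.frame of [rt_trial()] rows.
#' @return List with `mean_rt` (seconds, over accepted trials), `n_accepted`,
#'   `n_rejected`, and the per-trial `table`.
#' @export
session_rt <- function(trials) {
  acc <- !trials$rejected
  if (!any(acc)) stop("no accepted trials in the session")
  list(mean_rt = mean(trials$rt[acc]), n_accepted = sum(acc),
       n_rejected = sum(!acc), table = trials)
}

#' Pre-reaction-time stimulation schedule
#'
#' Stimulus times for movement-preparation TMS probes, delivered at fixed
#' fractions of the participant's baseline mean reaction time after the cue.
#'
#' @param baseline_rt baseline mean reaction time in seconds.
#' @param fractions pre-RT fractions (default `c(0.5, 0.8)`).
#' @param go_time cue time the offsets are added to (default 0).
#' @return data.frame `fraction`, `stim_offset` (s after cue), `stim_time`.
#' @export
#' @examples
#' pre_rt_times(0.2)   # offsets 0.10 and 0.16 s
pre_rt_times <- function(baseline_rt, fractions = c(0.5, 0.8), go_time = 0) {
  if (baseline_rt <= 0) stop("`baseline_rt` must be positive")
  if (any(fractions <= 0 | fractions >= 1))
    stop("`fractions` must lie strictly between 0 and 1")
  data.frame(fraction = fractions, stim_offset = fractions * baseline_rt,
             stim_time = go_time + fractions * baseline_rt)
}
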