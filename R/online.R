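#' Large-Laplacian spatial filter specification
#'
#' The online chain re-references the target channel by the mean of its six
#' surrounding electrodes (weights +1 on the centre, -1/6 on each neighbour).
#' The weights sum to zero, so any channel-constant offset — e.g. a common-mode
#' component shared by all electrodes — is cancelled exactly.
#'
#' @param center centre channel label.
#' @param neighbors character vector of six distinct neighbour labels.
#' @return A `laplacian_spec` list.
#' @export
laplacian_spec <- function(center, neighbors) {
  neighbors <- as.character(neighbors)
  if (length(neighbors) != 6L) stop("exactly six neighbours are required")
  if (anyDuplicated(neighbors)) stop("duplicate neighbour channel")
  if (center %in% neighbors) stop("neighbours must exclude the centre channel")
  structure(list(center = center, neighbors = neighbors),
            class = "laplacian_spec")
}

#' Apply a large-Laplacian re-reference
#'
#' @param rec a [recording()] containing the centre and all neighbour
#'   channels.
#' @param spec a [laplacian_spec()].
#' @return A single-channel [recording()] labelled
#'   `<center>-lap` with `out[t] = center[t] - mean(neighbors[t])`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(7000), 7), 1000,
#'                  labels = c("C3", paste0("n", 1:6)))
#' lap <- apply_laplacian(rec, laplacian_spec("C3", paste0("n", 1:6)))
apply_laplacian <- function(rec, spec) {
  stopifnot(inherits(spec, "laplacian_spec"))
  missing <- setdiff(c(spec$center, spec$neighbors), rec$labels)
  if (length(missing))
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  out <- rec$data[spec$center, ] -
    colMeans(rec$data[spec$neighbors, , drop = FALSE])
  recording(out, rec$srate, paste0(spec$center, "-lap"),
            rec$start_time, rec$meta)
}

#' Online scoring configuration
#'
#' Parameters of the causal feedback chain: 1-s sliding spectral window updated
#' every 100 ms (adjacent windows overlap 90%), Hanning taper, 1–70 Hz
#' fourth-order Butterworth band-pass plus 50 Hz notch, and a feedback score
#' clipped to 0–100%.
#'
#' @param window_len spectral window length in seconds (default 1).
#' @param update_step score update interval in seconds (default 0.1).
#' @param bandpass band-pass edges in Hz (default `c(1, 70)`).
#' @param bp_order band-pass order (default 4).
#' @param notch_freq notch centre in Hz (default 50).
#' @param notch_q notch quality factor (default 30).
#' @param score_clip feedback clipping range in percent (default `c(0, 100)`).
#' @param warmup seconds excluded from scoring at session start while the
#'   causal filter settles (default 1).
#' @return An `online_config` list.
#' @export
online_config <- function(window_len = 1, update_step = 0.1,
                          bandpass = c(1, 70), bp_order = 4,
                          notch_freq = 50, notch_q = 30,
                          score_clip = c(0, 100), warmup = 1) {
  if (update_step > window_len)
    stop("`update_step` must not exceed `window_len`")
  structure(as.list(environment()), class = "online_config")
}

#' The SMR-ERD feedback formula
#'
#' `ERD = (R - A) / R * 100`, the percent attenuation of band power `A`
#' relative to the resting baseline `R`. Positive values mean
#' desynchronization. The feedback score shown to a participant is the raw
#' value clipped to `clip`; the raw value is what offline analyses consume.
#'
#' @param A band power (or vector of band powers) at time t.
#' @param R baseline band power; must be positive.
#' @param clip clipping range for the feedback score.
#' @return A data.frame with columns `raw` and `score`.
#' @export
#' @examples
#' erd_score(c(10, 0, 15), R = 10)
erd_score <- function(A, R, clip = c(0, 100)) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    stop("baseline band power `R` must be a single positive number")
  raw <- (R - A) / R * 100
  data.frame(raw = raw, score = pmin(pmax(raw, clip[1]), clip[2]))
}

#' Run the full online feedback session on a recording
#'
#' Causal real-time-equivalent scoring: large Laplacian, causal band-pass and
#' notch, trailing 1-s Hanning sliding PSD every 100 ms, band-mean power across
#' the calibrated individual alpha band, and the ERD formula against the
#' calibrated baseline. Scores are emitted only for windows lying wholly
#' inside imagery epochs; the per-trial score is the mean over those windows.
#'
#' @param rec a [recording()] of the session.
#' @param calib a [calibration_result()].
#' @param schedule a [trial_schedule()].
#' @param cfg an [online_config()].
#' @return An `online_session`: list with `grid` (data.frame `time`, `raw_erd`,
#'   `score`, `trial`; all scored windows), `trials` (data.frame `trial`,
#'   `mean_score`, `mean_raw_erd`), and `band`.
#' @export
run_online_session <- function(rec, calib, schedule, cfg = online_config()) {
  stopifnot(inherits(calib, "calibration_result"))
  validate_schedule(schedule)
  lap <- apply_laplacian(rec, calib$laplacian)
  filt <- causal_filter(lap, cfg$bandpass[1], cfg$bandpass[2], cfg$bp_order,
                        cfg$notch_freq, cfg$notch_q)
  est <- sliding_psd(filt, cfg$window_len, cfg$update_step, align = "trailing")
  if (calib$iaf_band[2] > max(est$freqs))
    stop("calibrated band exceeds the spectral range of the estimator")
  A <- band_power(est, calib$iaf_band)
  R <- baseline_band_power(calib, calib$iaf_band)
  sc <- erd_score(A, R, cfg$score_clip)

  ok <- est$times >= rec$start_time + cfg$warmup + cfg$window_len - 1e-9
  imag <- windows_within(est, schedule$imagery_onset, schedule$imagery_end)
  keep <- ok & imag
  trial <- findInterval(est$times, schedule$imagery_onset)
  grid <- data.frame(time = est$times[keep], raw_erd = sc$raw[keep],
                     score = sc$score[keep], trial = trial[keep])
  trials <- data.frame(
    trial = schedule$trial,
    mean_score = vapply(schedule$trial, function(i)
      mean(grid$score[grid$trial == i]), numeric(1)),
    mean_raw_erd = vapply(schedule$trial, function(i)
      mean(grid$raw_erd[grid$trial == i]), numeric(1))
  )
  structure(list(grid = grid, trials = trials, band = calib$iaf_band),
            class = "online_session")
}

#' @export
print.online_session <- function(x, ...) {
  cat(sprintf("<online_session> %d trials, band %g-%g Hz, mean score %.1f%%\n",
              nrow(x$trials), x$band[1], x$band[2], mean(x$trials$mean_score)))
  invisible(x)
}

#' Yoked-sham feedback replay
#'
#' Placebo feedback: the recipient's screen shows another participant's score
#' sequence, trial for trial, decoupled from the recipient's own EEG. Trial i
#' of the donor maps to trial i of the recipient.
#'
#' @param donor an `online_session` from [run_online_session()] (the donor's
#'   veritable feedback).
#' @param n_trials number of recipient trials to serve.
#' @return A list with `trials` (donor per-trial mean scores, re-indexed to
#'   the recipient's trials) and `grid` (donor score samples, trial-indexed).
#' @export
sham_replay <- function(donor, n_trials) {
  if (!inherits(donor, "online_session")) stop("`donor` must be an online_session")
  if (n_trials < 1) stop("`n_trials` must be at least 1")
  if (nrow(donor$trials) < n_trials)
    stop("donor session has ", nrow(donor$trials),
         " trials; recipient needs ", n_trials)
  trials <- donor$trials[seq_len(n_trials), c("trial", "mean_score")]
  grid <- donor$grid[donor$grid$trial %in% seq_len(n_trials),
                     c("trial", "time", "score")]
  list(trials = trials, grid = grid)
}
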