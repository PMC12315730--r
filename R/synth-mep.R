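#' Configuration for the synthetic MEP generator
#'
#' A motor-evoked potential is modelled as a damped oscillation starting about
#' 20 ms after the TMS pulse, riding on Gaussian noise. The noise-free
#' waveform is scaled so that its peak-to-peak amplitude equals `ptp_true`
#' exactly, which makes the downstream peak-to-peak operation a round trip.
#'
#' @param ptp_true target peak-to-peak amplitude in mV.
#' @param stim_time stimulus time in seconds from trace start (default 0.1, so
#'   the canonical -100..+150 ms segmentation spans the whole trace).
#' @param duration trace length in seconds (default 0.25).
#' @param mep_onset response latency after the stimulus in seconds
#'   (default 0.020).
#' @param mep_freq oscillation frequency of the waveform in Hz (default 80;
#'   kept away from the 50 Hz notch).
#' @param damping exponential decay rate in 1/s (default 100).
#' @param noise_sd additive Gaussian noise standard deviation in mV
#'   (default 0).
#' @param srate sampling rate in Hz (default 10000).
#' @param seed integer seed or `NULL`.
#' @return A validated `mep_gen_config` list.
#' @export
mep_gen_config <- function(ptp_true, stim_time = 0.1, duration = 0.25,
                           mep_onset = 0.020, mep_freq = 80, damping = 100,
                           noise_sd = 0, srate = 10000, seed = NULL) {
  if (ptp_true <= 0) stop("`ptp_true` must be positive")
  if (stim_time < 0 || stim_time >= duration)
    stop("`stim_time` must fall inside the trace")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(as.list(environment()), class = "mep_gen_config")
}

#' Generate one synthetic MEP sweep
#'
#' @param cfg a [mep_gen_config()].
#' @return A single-channel [recording()] in uV (label `"EDC"`), with
#'   `meta$ground_truth` holding `ptp_true` (mV) and the stimulus time.
#' @export
#' @examples
#' sweep <- generate_mep(mep_gen_config(ptp_true = 1))
#' # noise-free round trip:
#' diff(range(sweep$data)) / 1000  # 1 mV
generate_mep <- function(cfg) {
  stopifnot(inherits(cfg, "mep_gen_config"))
  use_seed(cfg$seed)
  n <- round(cfg$duration * cfg$srate)
  tt <- (seq_len(n) - 1) / cfg$srate
  t0 <- cfg$stim_time + cfg$mep_onset
  tau <- tt - t0
  u <- ifelse(tau >= 0,
              exp(-cfg$damping * tau) * sin(2 * pi * cfg$mep_freq * tau), 0)
  scale_uV <- cfg$ptp_true * 1000 / (max(u) - min(u))
  x <- u * scale_uV
  if (cfg$noise_sd > 0)
    x <- x + stats::rnorm(n) * cfg$noise_sd * 1000
  truth <- list(ptp_true = cfg$ptp_true, stim_time = cfg$stim_time,
                mep_onset = cfg$mep_onset, seed = cfg$seed)
  recording(x, cfg$srate, "EDC",
            meta = list(ground_truth = truth, config = cfg))
}

#' Generate a labelled set of MEP sweeps for a SICI session
#'
#' Draws `n_per_cell` sweeps for every (protocol, condition) cell of a
#' peak-to-peak amplitude table, emulating one participant's TMS evaluation.
#'
#' @param ptp_table data.frame with columns `protocol` (`"single"`/`"paired"`),
#'   `condition` (`"rest"`, `"rt50"`, `"rt80"`), `ptp` (mV).
#' @param n_per_cell sweeps per cell (default 7, the per-condition repetition
#'   count of the movement-preparation protocol).
#' @param noise_sd additive noise sd in mV (default 0).
#' @param seed integer seed or `NULL`.
#' @param ... further arguments passed to [mep_gen_config()].
#' @return A data.frame with columns `protocol`, `condition`, `sweep`, and a
#'   list-column `rec` of [recording()] objects.
#' @export
generate_mep_set <- function(ptp_table, n_per_cell = 7, noise_sd = 0,
                             seed = NULL, ...) {
  stopifnot(all(c("protocol", "condition", "ptp") %in% names(ptp_table)))
  use_seed(seed)
  rows <- ptp_table[rep(seq_len(nrow(ptp_table)), each = n_per_cell), ]
  rows$sweep <- rep(seq_len(n_per_cell), times = nrow(ptp_table))
  rows$rec <- lapply(rows$ptp, function(p) {
    generate_mep(mep_gen_config(ptp_true = p, noise_sd = noise_sd,
                                seed = NULL, ...))
  })
  rownames(rows) <- NULL
  rows
}
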