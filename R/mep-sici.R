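#' MEP preprocessing and segmentation
#'
#' Band-pass (10–450 Hz, fourth-order Butterworth, single-pass) plus 50 Hz
#' notch filtering of an EMG sweep, then segmentation to the canonical window
#' from 100 ms before to 150 ms after the stimulus. Optional stimulus-artifact
#' blanking zeroes the samples within `blank` seconds of the stimulus before
#' filtering to suppress ringing; it is off by default, as synthetic sweeps
#' carry no pulse artifact.
#'
#' @param rec single-channel EMG [recording()] in uV.
#' @param stim_time stimulus time in seconds.
#' @param low,high band-pass edges in Hz (defaults 10 and 450).
#' @param order filter order (default 4).
#' @param notch_freq notch centre in Hz or `NULL` (default 50).
#' @param pre,post segment extent around the stimulus in seconds (defaults
#'   0.1 and 0.15).
#' @param blank half-width of stimulus blanking in seconds, or `NULL`
#'   (default) to skip.
#' @return A `mep_segment`: single-channel [recording()] re-timed so the
#'   stimulus sits at t = 0, with `meta$stim_time = 0`.
#' @export
preprocess_mep <- function(rec, stim_time, low = 10, high = 450, order = 4,
                           notch_freq = 50, pre = 0.1, post = 0.15,
                           blank = NULL) {
  if (rec$srate < 1000) stop("MEP preprocessing expects srate >= 1 kHz")
  if (!is.null(blank)) {
    tt <- sample_times(rec)
    rec$data[, abs(tt - stim_time) <= blank] <- 0
  }
  filt <- causal_filter(rec, low, high, order, notch_freq)
  tt <- sample_times(filt)
  keep <- tt >= stim_time - pre - 1e-9 & tt < stim_time + post - 1e-9
  dt <- 1 / rec$srate
  if (tt[1] > stim_time - pre + 1e-9 ||
      tt[length(tt)] < stim_time + post - dt - 1e-9)
    stop("segment [", -pre, ", ", post, "] s around the stimulus exceeds the trace")
  seg <- recording(filt$data[, keep, drop = FALSE], filt$srate, filt$labels,
                   start_time = -pre, meta = rec$meta)
  seg$meta$stim_time <- 0
  class(seg) <- c("mep_segment", class(seg))
  seg
}

#' Peak-to-peak MEP amplitude
#'
#' `max - min` of the trace within a post-stimulus search window (default
#' 15–60 ms, the canonical forearm MEP latency range), returned in mV.
#'
#' @param seg a `mep_segment` (stimulus at t = 0) or any single-channel
#'   [recording()] in uV.
#' @param search_window length-2 numeric, seconds after the stimulus
#'   (default `c(0.015, 0.060)`).
#' @return Peak-to-peak amplitude in mV.
#' @export
#' @examples
#' sweep <- generate_mep(mep_gen_config(ptp_true = 1))
#' seg <- preprocess_mep(sweep, stim_time = 0.1)
#' peak_to_peak(seg)
peak_to_peak <- function(seg, search_window = c(0.015, 0.060)) {
  tt <- sample_times(seg)
  sel <- tt >= search_window[1] & tt <= search_window[2]
  if (!any(sel)) stop("empty search window [", search_window[1], ", ",
                      search_window[2], "] s")
  x <- seg$data[1L, sel]
  (max(x) - min(x)) / 1000
}

#' Per-condition MEP means
#'
#' Arithmetic mean peak-to-peak amplitude for every (protocol, condition)
#' cell.
#'
#' @param sweeps data.frame with columns `protocol` (`"single"`/`"paired"`),
#'   `condition`, and `ptp` (mV).
#' @param required optional data.frame of (protocol, condition) cells that
#'   must be present; an informative error names any empty cell.
#' @return data.frame `protocol`, `condition`, `mean_ptp`, `n`.
#' @export
condition_means <- function(sweeps, required = NULL) {
  stopifnot(all(c("protocol", "condition", "ptp") %in% names(sweeps)))
  agg <- stats::aggregate(ptp ~ protocol + condition, data = sweeps,
                          FUN = mean)
  names(agg)[3] <- "mean_ptp"
  agg$n <- stats::aggregate(ptp ~ protocol + condition, data = sweeps,
                            FUN = length)$ptp
  if (!is.null(required)) {
    key <- paste(agg$protocol, agg$condition)
    want <- paste(required$protocol, required$condition)
    missing <- setdiff(want, key)
    if (length(missing))
      stop("no sweeps for cell(s): ", paste(missing, collapse = "; "))
  }
  agg
}

#' SICI percentage per condition
#'
#' Short-interval intracortical inhibition, expressed as the paired-pulse mean
#' MEP amplitude as a percentage of the single-pulse mean:
#' `SICI = mean_paired / mean_single * 100`. Lower values mean stronger
#' inhibition; a pre-to-post increase (`delta = post - pre`) is inhibition
#' release.
#'
#' @param means data.frame from [condition_means()] containing both protocols
#'   for each condition of interest.
#' @return A `sici_result` data.frame: `condition`, `mean_single`,
#'   `mean_paired`, `sici_percent`.
#' @export
#' @examples
#' m <- data.frame(protocol = c("single", "paired"), condition = "rest",
#'                 mean_ptp = c(1.0, 0.5))
#' sici(m)
sici <- function(means) {
  conds <- unique(means$condition)
  rows <- lapply(conds, function(cc) {
    s <- means$mean_ptp[means$protocol == "single" & means$condition == cc]
    p <- means$mean_ptp[means$protocol == "paired" & means$condition == cc]
    if (!length(s) || !length(p))
      stop("condition `", cc, "` lacks a ", if (!length(s)) "single" else "paired",
           "-pulse cell")
    data.frame(condition = cc, mean_single = s, mean_paired = p,
               sici_percent = p / s * 100)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sici_result", "data.frame")
  out
}

#' SICI evaluation from raw sweeps
#'
#' Full chain for one participant's TMS session: preprocess and segment every
#' sweep, quantify peak-to-peak amplitudes, average per cell, and compute the
#' per-condition SICI percentages. Participant-level quality flags (absence of
#' resting SICI) are attached rather than silently dropping data.
#'
#' @param sweep_df data.frame with columns `protocol`, `condition`, and a
#'   list-column `rec` of raw sweeps (as from [generate_mep_set()]).
#' @param stim_time stimulus time within each sweep in seconds (default 0.1).
#' @param search_window passed to [peak_to_peak()].
#' @param ... passed to [preprocess_mep()].
#' @return List with `sici` (a [sici()] table), `means`, `ptp` (per-sweep
#'   amplitudes), and `qc` (flags).
#' @export
sici_from_sweeps <- function(sweep_df, stim_time = 0.1,
                             search_window = c(0.015, 0.060), ...) {
  sweep_df$ptp <- vapply(sweep_df$rec, function(r) {
    peak_to_peak(preprocess_mep(r, stim_time, ...), search_window)
  }, numeric(1))
  means <- condition_means(sweep_df[c("protocol", "condition", "ptp")])
  res <- sici(means)
  qc <- list(no_resting_sici =
               "rest" %in% res$condition &&
               res$sici_percent[res$condition == "rest"] >= 100)
  list(sici = res, means = means, ptp = sweep_df[names(sweep_df) != "rec"],
       qc = qc)
}
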