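#' Offline preprocessing: zero-phase filtering and channel exclusion
#'
#' 3–40 Hz fourth-order zero-phase Butterworth band-pass plus 50 Hz notch,
#' after dropping an optional artifact-prone channel set (e.g. periocular /
#' auricular electrodes). Forward-backward filtering leaves no phase shift.
#'
#' @param rec a [recording()].
#' @param low,high band-pass edges in Hz (defaults 3 and 40).
#' @param order overall forward filter order (default 4).
#' @param notch_freq notch centre in Hz or `NULL` (default 50).
#' @param exclude_channels labels to drop before filtering (default none;
#'   labels absent from the montage are ignored).
#' @return The preprocessed [recording()].
#' @export
preprocess_offline <- function(rec, low = 3, high = 40, order = 4,
                               notch_freq = 50, exclude_channels = NULL) {
  if (rec$srate < 100) stop("offline preprocessing expects srate >= 100 Hz")
  if (!is.null(exclude_channels)) {
    drop <- intersect(exclude_channels, rec$labels)
    if (length(drop)) rec <- drop_channels(rec, drop)
  }
  zero_phase_filter(rec, low, high, order, notch_freq)
}

#' Segment a recording into per-trial epochs
#'
#' Each trial's epoch spans its resting-epoch onset through imagery end plus
#' `tail_dur` seconds (default 1). Epoch recordings are re-timed to start at
#' 0 s and carry their trial's relative epoch boundaries in
#' `meta$epoch`.
#'
#' @param rec a [recording()].
#' @param schedule a [trial_schedule()].
#' @param tail_dur seconds appended after imagery end (default 1).
#' @return A list of [recording()] epochs, one per trial.
#' @export
segment_epochs <- function(rec, schedule, tail_dur = 1) {
  validate_schedule(schedule)
  srate <- rec$srate
  n <- n_samples(rec)
  lapply(seq_len(nrow(schedule)), function(i) {
    t0 <- schedule$rest_onset[i]
    t1 <- schedule$imagery_end[i] + tail_dur
    i0 <- round((t0 - rec$start_time) * srate) + 1L
    i1 <- round((t1 - rec$start_time) * srate)
    if (i0 < 1L || i1 > n)
      stop("trial ", schedule$trial[i], " segment [", t0, ", ", t1,
           "] s exceeds the recording")
    ep <- recording(rec$data[, i0:i1, drop = FALSE], srate, rec$labels)
    ep$meta$epoch <- list(
      trial = schedule$trial[i],
      ready_onset = schedule$ready_onset[i] - t0,
      imagery_onset = schedule$imagery_onset[i] - t0,
      imagery_end = schedule$imagery_end[i] - t0)
    ep
  })
}

#' Amplitude-threshold bad-trial rejection
#'
#' Drops epochs whose peak absolute amplitude on any channel exceeds
#' `threshold` (default 200 uV) and logs every decision.
#'
#' @param epochs list of epochs from [segment_epochs()].
#' @param threshold rejection threshold in uV (default 200; `Inf` disables).
#' @return List with `epochs` (retained) and `log` (data.frame `trial`,
#'   `peak_uV`, `rejected`, `reason`). Errors if every trial is rejected.
#' @export
reject_bad_trials <- function(epochs, threshold = 200) {
  if (!length(epochs)) stop("no epochs supplied")
  peaks <- vapply(epochs, function(ep) max(abs(ep$data)), numeric(1))
  trials <- vapply(epochs, function(ep) ep$meta$epoch$trial, numeric(1))
  bad <- peaks > threshold
  log <- data.frame(trial = trials, peak_uV = peaks, rejected = bad,
                    reason = ifelse(bad,
                                    sprintf("peak %.1f uV > %g uV", peaks,
                                            threshold), ""))
  if (all(bad))
    stop("all ", length(epochs), " trials rejected at threshold ", threshold,
         " uV (peaks ", paste(round(peaks), collapse = ", "), ")")
  list(epochs = epochs[!bad], log = log)
}

svd_decompose <- function(X) {
  s <- svd(X)                      # X = U D V', components in rows of D V'
  list(mixing = s$u, sources = diag(s$d, nrow = length(s$d)) %*% t(s$v))
}

#' Template-correlated component removal (artifact hook)
#'
#' Pluggable artifact-removal stage. Disabled (the default, appropriate for
#' synthetic data) it is a bit-identical pass-through. Enabled, each epoch is
#' decomposed into components, components whose time courses correlate with
#' the supplied artifact template at `|r| > r_thresh` are zeroed, and the rest
#' are back-projected. The default decomposition is the SVD (principal
#' components); any factorization with the same `(mixing, sources)` contract —
#' e.g. an ICA — can be plugged in via `decompose`.
#'
#' @param epochs list of epochs.
#' @param enabled run the removal (default `FALSE`).
#' @param template numeric artifact time course, one value per epoch sample;
#'   required when enabled.
#' @param r_thresh absolute correlation above which a component is removed
#'   (default 0.8).
#' @param decompose function `matrix -> list(mixing, sources)` (default SVD).
#' @return List with `epochs` and `removed` (per-epoch count of removed
#'   components).
#' @export
artifact_removal_hook <- function(epochs, enabled = FALSE, template = NULL,
                                  r_thresh = 0.8, decompose = svd_decompose) {
  if (!enabled) return(list(epochs = epochs, removed = rep(0L, length(epochs))))
  if (is.null(template))
    stop("an artifact `template` is required when the hook is enabled")
  removed <- integer(length(epochs))
  out <- lapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]
    if (length(template) != n_samples(ep))
      stop("template length (", length(template),
           ") must match epoch samples (", n_samples(ep), ")")
    mu <- rowMeans(ep$data)
    dec <- decompose(ep$data - mu)
    r <- abs(apply(dec$sources, 1L, stats::cor, y = template))
    drop <- which(is.finite(r) & r > r_thresh)
    removed[i] <<- length(drop)
    keep <- dec$sources
    if (length(drop)) keep[drop, ] <- 0
    ep$data <- dec$mixing %*% keep + mu
    rownames(ep$data) <- ep$labels
    ep
  })
  list(epochs = out, removed = removed)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean of the output is identically zero and any channel-constant
#' offset is cancelled.
#'
#' @param x a [recording()] or a list of them.
#' @return Same shape as `x`, re-referenced.
#' @export
common_average_reference <- function(x) {
  if (is.list(x) && !inherits(x, "recording"))
    return(lapply(x, common_average_reference))
  if (nrow(x$data) < 2L)
    stop("common average reference needs at least 2 channels")
  x$data <- sweep(x$data, 2L, colMeans(x$data))
  x
}

#' Per-trial ERSP maps and band outcomes
#'
#' Short-time Fourier analysis of each epoch's target channel (centre-aligned
#' 1-s Hanning windows, 90% overlap at the default 0.1-s step). The baseline
#' `R(f)` is the per-frequency median PSD over the resting-epoch windows of
#' the whole trial set, so the block is self-contained. The ERSP map is
#' `(A(f,t) - R(f)) / R(f) * 100` — negative values are desynchronization.
#'
#' The scalar per-trial band outcome averages band power first and then takes
#' the same ratio (band-mean-then-ratio, matching the online score), over
#' windows lying wholly inside the imagery epoch (`summary_window`, seconds
#' after imagery onset).
#'
#' @param epochs list of epochs (preprocessed, re-referenced).
#' @param target_channel channel to analyze (e.g. `"C3"`).
#' @param bands named list of length-2 numeric band edges in Hz (e.g.
#'   `list(iaf = c(9, 12), ibf = c(19, 23))`); all must lie within the 3–40 Hz
#'   analysis band.
#' @param window_len,step STFT window and hop in seconds (defaults 1 and 0.1).
#' @param summary_window imagery-epoch averaging window in seconds after
#'   imagery onset (default `c(0.5, 4.5)`: every contributing 1-s window lies
#'   wholly inside the 5-s imagery epoch).
#' @return List with `maps` (per-trial `ersp_map`: `values` freq x time in %,
#'   `freqs`, `times`), `trial_band` (data.frame `trial` + one column per
#'   band), `baseline` (R(f)), `freqs`.
#' @export
compute_ersp <- function(epochs, target_channel, bands,
                         window_len = 1, step = 0.1,
                         summary_window = c(0.5, 4.5)) {
  if (!length(epochs)) stop("no epochs supplied")
  for (b in bands)
    if (b[1] < 3 || b[2] > 40)
      stop("band [", b[1], ", ", b[2], "] Hz outside the 3-40 Hz analysis band")
  ests <- lapply(epochs, function(ep) {
    sliding_psd(pick_channels(ep, target_channel), window_len, step,
                align = "center")
  })
  freqs <- ests[[1]]$freqs

  rest_cols <- lapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]$meta$epoch
    ests[[i]]$power[, windows_within(ests[[i]], 0, ep$ready_onset),
                    drop = FALSE]
  })
  rest_pool <- do.call(cbind, rest_cols)
  if (!ncol(rest_pool)) stop("no complete resting windows for the baseline")
  R <- apply(rest_pool, 1L, stats::median)

  maps <- lapply(seq_along(epochs), function(i) {
    vals <- (ests[[i]]$power - R) / R * 100
    structure(list(values = vals, freqs = freqs, times = ests[[i]]$times,
                   baseline_ref = "rest-epoch median PSD"),
              class = "ersp_map")
  })

  band_sel <- lapply(bands, function(b) freqs >= b[1] & freqs <= b[2])
  trial_band <- data.frame(trial = vapply(epochs, function(ep)
    ep$meta$epoch$trial, numeric(1)))
  for (bn in names(bands)) {
    sel <- band_sel[[bn]]
    # median over rest windows of the band-mean power: the same statistic as
    # the numerator, so the ratio is unbiased where no rhythm sits (a per-bin
    # median of the exponentially distributed periodogram would sit ln 2
    # below the mean band power and fabricate spurious positive ERSP there)
    Rbar <- stats::median(colMeans(rest_pool[sel, , drop = FALSE]))
    trial_band[[bn]] <- vapply(seq_along(epochs), function(i) {
      ep <- epochs[[i]]$meta$epoch
      win <- windows_within(ests[[i]], ep$imagery_onset + summary_window[1] -
                              window_len / 2,
                            ep$imagery_onset + summary_window[2] +
                              window_len / 2)
      Abar <- mean(ests[[i]]$power[sel, win, drop = FALSE])
      (Abar - Rbar) / Rbar * 100
    }, numeric(1))
  }
  list(maps = maps, trial_band = trial_band, baseline = R, freqs = freqs)
}

#' Median-over-trials block summary
#'
#' The per-block outcome feeding the group statistics: the median across
#' trials of each per-trial band ERSP.
#'
#' @param ersp result of [compute_ersp()].
#' @param participant,block identifiers stored in the output row.
#' @return One-row data.frame: `participant`, `block`, and `ersp_<band>`
#'   medians.
#' @export
block_summary <- function(ersp, participant = NA, block = NA) {
  tb <- ersp$trial_band
  out <- data.frame(participant = participant, block = block)
  for (bn in setdiff(names(tb), "trial"))
    out[[paste0("ersp_", bn)]] <- stats::median(tb[[bn]])
  out
}

#' Full offline ERSP evaluation of one block
#'
#' Convenience chain: offline preprocessing, epoch segmentation, bad-trial
#' rejection, artifact hook, common average reference, per-trial ERSP, and the
#' median block summary at the calibrated IAF and IBF bands.
#'
#' @param rec raw block [recording()].
#' @param schedule the block's [trial_schedule()].
#' @param calib a [calibration_result()] providing the bands and the target
#'   channel (the Laplacian centre).
#' @param reject_threshold bad-trial threshold in uV (default 200).
#' @param hook_args list of arguments for [artifact_removal_hook()].
#' @param ... passed to [compute_ersp()].
#' @return List with `summary` (one-row block summary), `ersp`
#'   (per-trial detail), `rejection_log`.
#' @export
offline_ersp_block <- function(rec, schedule, calib, reject_threshold = 200,
                               hook_args = list(), ...) {
  pre <- preprocess_offline(rec)
  epochs <- segment_epochs(pre, schedule)
  kept <- reject_bad_trials(epochs, reject_threshold)
  hooked <- do.call(artifact_removal_hook, c(list(epochs = kept$epochs),
                                             hook_args))
  refd <- common_average_reference(hooked$epochs)
  bands <- list(iaf = calib$iaf_band, ibf = calib$ibf_band)
  ersp <- compute_ersp(refd, calib$laplacian$center, bands, ...)
  list(summary = block_summary(ersp), ersp = ersp, rejection_log = kept$log)
}
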