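#' Per-participant spectral calibration result
#'
#' Holds the resting baseline spectrum and the participant-specific scoring
#' bands derived from a no-feedback evaluation block: the per-frequency median
#' resting PSD `R(f)`, the individual alpha frequency (IAF) band — the most
#' pronounced contiguous 3 Hz of desynchronization within 8–13 Hz — and the
#' individual beta frequency (IBF) band, twice the IAF band centre plus/minus
#' 2 Hz.
#'
#' @param R numeric vector, median resting PSD per frequency bin (uV^2/Hz).
#' @param freqs frequency-bin centres matching `R`, in Hz.
#' @param iaf_band length-2 numeric, IAF band edges in Hz (width 3, inside
#'   8–13).
#' @param iaf_median IAF band centre frequency in Hz.
#' @param ibf_band length-2 numeric, IBF band edges in Hz.
#' @param laplacian a [laplacian_spec()] naming the scored channel set.
#' @return A `calibration_result` list.
#' @export
calibration_result <- function(R, freqs, iaf_band, iaf_median, ibf_band,
                               laplacian) {
  if (length(R) != length(freqs)) stop("`R` and `freqs` lengths differ")
  if (iaf_band[1] < 8 || iaf_band[2] > 13 ||
      abs(diff(iaf_band) - 3) > 1e-9)
    stop("IAF band must be a 3-Hz-wide interval within 8-13 Hz")
  scored <- freqs >= iaf_band[1] & freqs <= iaf_band[2]
  if (any(R[scored] <= 0))
    stop("baseline spectrum must be positive on all scored bins")
  structure(list(R = R, freqs = freqs, iaf_band = iaf_band,
                 iaf_median = iaf_median, ibf_band = ibf_band,
                 laplacian = laplacian),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> IAF %g-%g Hz (median %g), IBF %g-%g Hz, centre %s\n",
              x$iaf_band[1], x$iaf_band[2], x$iaf_median,
              x$ibf_band[1], x$ibf_band[2], x$laplacian$center))
  invisible(x)
}

#' Baseline band power from a calibration
#'
#' Band-mean of the stored median resting spectrum — the scalar `R` the ERD
#' formula divides by.
#'
#' @param calib a [calibration_result()].
#' @param band length-2 numeric band edges in Hz (defaults to the IAF band).
#' @return A single band power in uV^2/Hz.
#' @export
baseline_band_power <- function(calib, band = calib$iaf_band) {
  sel <- calib$freqs >= band[1] & calib$freqs <= band[2]
  if (!any(sel)) stop("band contains no calibrated frequency bins")
  mean(calib$R[sel])
}

#' Select the individual alpha frequency band
#'
#' Finds the contiguous 3-Hz window within 8–13 Hz whose mean ERD is largest
#' (most pronounced desynchronization). On the 1-Hz frequency grid the
#' admissible candidates are the integer-edged windows 8–11, 9–12, and 10–13;
#' ties resolve to the lowest-frequency window.
#'
#' @param erd_by_freq numeric vector of mean ERD (%) per 1-Hz bin, named by
#'   frequency, covering at least integer bins 8..13.
#' @return List with `band` (length-2 numeric), `median` (band centre, Hz),
#'   and `mean_erd` (the winning window's mean ERD).
#' @export
#' @examples
#' select_iaf(c(`8` = 5, `9` = 5, `10` = 30, `11` = 30, `12` = 30, `13` = 5))
select_iaf <- function(erd_by_freq) {
  need <- as.character(8:13)
  if (is.null(names(erd_by_freq)))
    names(erd_by_freq) <- as.character(seq(8, length.out = length(erd_by_freq)))
  if (!all(need %in% names(erd_by_freq)))
    stop("ERD values for integer bins 8..13 Hz are required")
  best_lo <- NA_integer_; best_mean <- -Inf
  for (lo in 8:10) {
    m <- mean(erd_by_freq[as.character(lo:(lo + 3))])
    if (m > best_mean) { best_mean <- m; best_lo <- lo }  # strict: tie keeps lower
  }
  band <- c(best_lo, best_lo + 3)
  list(band = band, median = mean(band), mean_erd = best_mean)
}

#' Derive the individual beta frequency band
#'
#' `IBF = 2 * iaf_median +/- 2` Hz.
#'
#' @param iaf_median IAF band centre in Hz; must lie in `[8, 13]`.
#' @return Length-2 numeric band edges in Hz.
#' @export
#' @examples
#' derive_ibf(11)   # 20 24
derive_ibf <- function(iaf_median) {
  if (iaf_median < 8 || iaf_median > 13)
    stop("`iaf_median` must lie in [8, 13] Hz")
  c(2 * iaf_median - 2, 2 * iaf_median + 2)
}

#' Calibrate scoring bands from a no-feedback evaluation block
#'
#' Runs the online chain (Laplacian, causal filters, trailing sliding PSD)
#' over the evaluation recording, takes the per-frequency median PSD of all
#' resting-epoch windows as the baseline `R(f)`, computes the mean ERD of the
#' imagery-epoch windows per 1-Hz bin over 8–13 Hz, and selects the IAF and
#' IBF bands. Recomputing on the same block is deterministic.
#'
#' @param rec evaluation-block [recording()].
#' @param schedule the block's [trial_schedule()].
#' @param laplacian a [laplacian_spec()]; by default the recording's first
#'   channel is the centre and the next six its neighbours.
#' @param cfg an [online_config()].
#' @return A [calibration_result()].
#' @export
calibrate <- function(rec, schedule, laplacian = NULL, cfg = online_config()) {
  validate_schedule(schedule)
  if (is.null(laplacian)) {
    if (length(rec$labels) < 7L)
      stop("default Laplacian needs at least 7 channels")
    laplacian <- laplacian_spec(rec$labels[1], rec$labels[2:7])
  }
  lap <- apply_laplacian(rec, laplacian)
  filt <- causal_filter(lap, cfg$bandpass[1], cfg$bandpass[2], cfg$bp_order,
                        cfg$notch_freq, cfg$notch_q)
  est <- sliding_psd(filt, cfg$window_len, cfg$update_step, align = "trailing")
  rest <- windows_within(est, schedule$rest_onset, schedule$ready_onset)
  imag <- windows_within(est, schedule$imagery_onset, schedule$imagery_end)
  if (!any(rest)) stop("no complete resting windows in the evaluation block")
  if (!any(imag)) stop("no complete imagery windows in the evaluation block")
  R <- compute_baseline(est, rest)

  bins <- 8:13
  idx <- match(bins, est$freqs)
  if (anyNA(idx)) stop("spectral grid lacks integer bins 8..13 Hz")
  erd_by_freq <- vapply(idx, function(i) {
    mean((R[i] - est$power[i, imag]) / R[i] * 100)
  }, numeric(1))
  names(erd_by_freq) <- as.character(bins)

  iaf <- select_iaf(erd_by_freq)
  calibration_result(R = R, freqs = est$freqs, iaf_band = iaf$band,
                     iaf_median = iaf$median,
                     ibf_band = derive_ibf(iaf$median), laplacian = laplacian)
}

#' Write / read a calibration as JSON
#'
#' @param calib a [calibration_result()].
#' @param path JSON file path.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` a [calibration_result()].
#' @export
write_calibration_json <- function(calib, path) {
  payload <- list(R = calib$R, freqs = calib$freqs,
                  iaf_band = calib$iaf_band, iaf_median = calib$iaf_median,
                  ibf_band = calib$ibf_band,
                  laplacian = list(center = calib$laplacian$center,
                                   neighbors = calib$laplacian$neighbors))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_result(R = p$R, freqs = p$freqs, iaf_band = p$iaf_band,
                     iaf_median = p$iaf_median, ibf_band = p$ibf_band,
                     laplacian = laplacian_spec(p$laplacian$center,
                                                p$laplacian$neighbors))
}
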