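#' Sliding-window power spectral density
#'
#' Short-time Fourier estimation as used both online and offline: a Hanning
#' taper of `window_len` seconds is slid along the signal in steps of
#' `step` seconds (adjacent windows overlap by `1 - step/window_len`, i.e. 90%
#' at the defaults), and each tapered segment is Fourier transformed into a
#' one-sided power spectral density in uV^2/Hz. With a 1-s window the frequency
#' resolution is 1 Hz.
#'
#' PSD scaling is the standard periodogram normalization
#' `P(f) = c |X(f)|^2 / (srate * sum(w^2))` with `c = 2` except at DC and
#' Nyquist, so that the PSD integrates to the mean tapered power.
#'
#' @param rec a single-channel [recording()].
#' @param window_len window length in seconds (default 1).
#' @param step hop between successive windows in seconds (default 0.1).
#' @param align `"trailing"` stamps each spectrum with the end of its window
#'   (causal, online convention); `"center"` with the window centre (offline
#'   convention).
#' @return A `spectral_estimate`: list with `power` (freq x time matrix,
#'   uV^2/Hz), `freqs` (Hz), `times` (s), `window_len`, `step`.
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:4999) / 1000), srate = 1000)
#' est <- sliding_psd(rec)
#' est$freqs[which.max(rowMeans(est$power))]  # 10
sliding_psd <- function(rec, window_len = 1, step = 0.1,
                        align = c("trailing", "center")) {
  align <- match.arg(align)
  if (nrow(rec$data) != 1L)
    stop("`sliding_psd` expects a single-channel recording")
  n <- n_samples(rec)
  nwin <- round(window_len * rec$srate)
  hop <- round(step * rec$srate)
  if (hop < 1 || nwin < 2) stop("window/step too small for this sampling rate")
  if (n < nwin) stop("signal (", n, " samples) shorter than one window (",
                     nwin, " samples)")
  starts <- seq(1L, n - nwin + 1L, by = hop)
  x <- rec$data[1L, ]
  w <- hanning_taper(nwin)
  # segment matrix: nwin x n_windows, tapered, one FFT batch
  idx <- outer(seq_len(nwin) - 1L, starts, `+`)
  seg <- matrix(x[idx], nrow = nwin) * w
  X <- stats::mvfft(seg)
  nf <- floor(nwin / 2) + 1L
  scale <- 2 / (rec$srate * sum(w^2))
  pw <- Mod(X[seq_len(nf), , drop = FALSE])^2 * scale
  pw[1L, ] <- pw[1L, ] / 2
  if (nwin %% 2 == 0) pw[nf, ] <- pw[nf, ] / 2
  freqs <- (seq_len(nf) - 1L) * rec$srate / nwin
  times <- rec$start_time + switch(align,
    trailing = (starts - 1L + nwin) / rec$srate,
    center   = (starts - 1L + nwin / 2) / rec$srate)
  structure(list(power = pw, freqs = freqs, times = times,
                 window_len = window_len, step = step, align = align),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d freq bins (%g-%g Hz) x %d windows, %s-aligned\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$align))
  invisible(x)
}

#' Symmetric Hanning taper
#'
#' `0.5 * (1 - cos(2*pi*k/(n-1)))`, k = 0..n-1; matches the taper the sliding
#' estimator applies, exposed so oracle computations can reuse it.
#'
#' @param n taper length in samples.
#' @return Numeric vector of length `n`.
#' @export
hanning_taper <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Band-averaged power from a spectral estimate
#'
#' Mean PSD across all frequency bins falling inside `band` (edges inclusive),
#' per window. This is the scalar band power A(f, t) that the ERD formula
#' consumes.
#'
#' @param est a [sliding_psd()] result.
#' @param band numeric length-2, band edges in Hz.
#' @return Numeric vector, one band power per window (uV^2/Hz).
#' @export
band_power <- function(est, band) {
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  if (!any(sel)) stop("band [", band[1], ", ", band[2],
                      "] Hz contains no frequency bins")
  colMeans(est$power[sel, , drop = FALSE])
}

#' Median baseline spectrum across resting windows
#'
#' Per-frequency median PSD over a collection of resting-epoch windows, pooled
#' across trials. The median (not the mean) makes the baseline robust to
#' occasional high-power windows.
#'
#' @param est a [sliding_psd()] result.
#' @param keep logical or integer index of windows belonging to resting
#'   epochs; defaults to all windows.
#' @return Numeric vector, one median power per frequency bin.
#' @export
compute_baseline <- function(est, keep = NULL) {
  pw <- est$power
  if (!is.null(keep)) pw <- pw[, keep, drop = FALSE]
  if (ncol(pw) == 0L) stop("no resting windows supplied to compute_baseline")
  apply(pw, 1L, stats::median)
}

#' Select windows whose full extent lies inside given intervals
#'
#' Helper for epoch bookkeeping: given window timestamps and the alignment used
#' to produce them, returns the windows entirely contained in any of the
#' `[onset, end]` intervals.
#'
#' @param est a [sliding_psd()] result.
#' @param onsets,ends interval bounds in seconds (parallel vectors).
#' @return Logical vector over windows.
#' @export
windows_within <- function(est, onsets, ends) {
  half <- est$window_len / 2
  lo <- switch(est$align, trailing = est$times - est$window_len,
               center = est$times - half)
  hi <- switch(est$align, trailing = est$times, center = est$times + half)
  out <- rep(FALSE, length(est$times))
  tol <- 1e-9
  for (i in seq_along(onsets)) {
    out <- out | (lo >= onsets[i] - tol & hi <= ends[i] + tol)
  }
  out
}
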