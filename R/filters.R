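#' Filter designs used across the pipeline
#'
#' All temporal filtering in the package is Butterworth band-pass plus a narrow
#' 50 Hz notch. `design_bandpass` follows the MATLAB/EEGLAB naming convention
#' common in this literature: a "fourth-order band-pass" is the band
#' transformation of an order-4 low-pass prototype (8 poles overall).
#' `design_notch` is the standard second-order IIR notch parameterized by
#' centre frequency and quality factor.
#'
#' @param low,high band edges in Hz.
#' @param srate sampling rate in Hz.
#' @param order prototype filter order (default 4).
#' @return An object of class `"Arma"` (coefficients `b`, `a`) as used by
#'   [signal::filter()].
#' @export
design_bandpass <- function(low, high, srate, order = 4) {
  nyq <- srate / 2
  if (high >= nyq) stop("upper cutoff (", high, " Hz) must be below Nyquist (",
                        nyq, " Hz)")
  if (low <= 0 || low >= high) stop("band edges must satisfy 0 < low < high")
  signal::butter(order, c(low, high) / nyq, type = "pass")
}

#' @rdname design_bandpass
#' @param freq notch centre frequency in Hz (default 50, mains).
#' @param q quality factor `freq / bandwidth` (default 30).
#' @export
design_notch <- function(freq = 50, srate = 1000, q = 30) {
  nyq <- srate / 2
  if (freq >= nyq) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  structure(list(b = b, a = a), class = "Arma")
}

# Single-pass IIR filtering (zero initial state), compiled inner loop.
iir_filter <- function(b, a, x) {
  .Call(C_iir_filter, as.double(b / a[1]), as.double(a / a[1]),
        as.double(x))
}

# Forward-backward pass of the same filter: squared magnitude response,
# zero phase.
iir_filtfilt <- function(b, a, x) {
  rev(iir_filter(b, a, rev(iir_filter(b, a, x))))
}

filter_matrix <- function(filt, data, zero_phase = FALSE) {
  fun <- if (zero_phase) iir_filtfilt else iir_filter
  out <- data
  for (ch in seq_len(nrow(data)))
    out[ch, ] <- fun(filt$b, filt$a, data[ch, ])
  out
}

#' Causal band-pass + notch filtering of a recording
#'
#' Single-pass (phase-lagging) filtering for the online chain: the output at
#' time t depends only on samples at times <= t, so the result is attainable in
#' a real-time system. Filter state spans the whole recording; no per-window
#' refiltering is performed.
#'
#' @param rec a [recording()].
#' @param low,high band-pass edges in Hz (defaults 1 and 70).
#' @param order overall band-pass order (default 4).
#' @param notch_freq notch centre in Hz, or `NULL` to skip (default 50).
#' @param notch_q notch quality factor (default 30).
#' @return The filtered [recording()].
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:999) / 1000), srate = 1000)
#' filt <- causal_filter(rec)
causal_filter <- function(rec, low = 1, high = 70, order = 4,
                          notch_freq = 50, notch_q = 30) {
  bp <- design_bandpass(low, high, rec$srate, order)
  out <- filter_matrix(bp, rec$data)
  if (!is.null(notch_freq)) {
    nt <- design_notch(notch_freq, rec$srate, notch_q)
    out <- filter_matrix(nt, out)
  }
  recording(out, rec$srate, rec$labels, rec$start_time, rec$meta)
}

#' Zero-phase band-pass + notch filtering of a recording
#'
#' Forward-backward filtering for offline analysis: no phase distortion, at the
#' price of using future samples. The quoted `order` is the overall forward
#' order; the forward-backward pass squares the magnitude response.
#'
#' @inheritParams causal_filter
#' @return The filtered [recording()].
#' @export
zero_phase_filter <- function(rec, low = 3, high = 40, order = 4,
                              notch_freq = 50, notch_q = 30) {
  bp <- design_bandpass(low, high, rec$srate, order)
  out <- filter_matrix(bp, rec$data, zero_phase = TRUE)
  if (!is.null(notch_freq)) {
    nt <- design_notch(notch_freq, rec$srate, notch_q)
    out <- filter_matrix(nt, out, zero_phase = TRUE)
  }
  recording(out, rec$srate, rec$labels, rec$start_time, rec$meta)
}

#' Magnitude response of a filter at given frequencies
#'
#' Analytic frequency response of an `Arma` design, used by the tests as the
#' oracle for attenuation claims.
#'
#' @param filt an `"Arma"` filter.
#' @param freqs frequencies in Hz.
#' @param srate sampling rate in Hz.
#' @return Numeric vector of magnitude responses (linear scale).
#' @export
filter_gain <- function(filt, freqs, srate) {
  z <- exp(-1i * 2 * pi * freqs / srate)
  num <- outer(z, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(z, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.numeric(Mod(num / den))
}
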