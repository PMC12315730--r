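#' Multichannel recording container
#'
#' A `recording` holds a channels-by-samples amplitude matrix in microvolts
#' together with its sampling rate and ordered channel labels. It is the common
#' currency of every stage in the package: synthetic generators return one,
#' spatial and temporal filters map one to another, and the spectral estimators
#' consume one.
#'
#' @param data numeric matrix, channels x samples, in microvolts. A plain
#'   vector is accepted for single-channel data.
#' @param srate sampling rate in samples per second.
#' @param labels character vector of unique channel names, one per row of
#'   `data`.
#' @param start_time time of the first sample in seconds (default 0).
#' @param meta optional named list of metadata (generators store their ground
#'   truth here).
#'
#' @return An object of class `recording` with elements `data`, `srate`,
#'   `labels`, `start_time`, `meta`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), srate = 1000,
#'                  labels = c("C3", "C4"))
#' n_samples(rec)
recording <- function(data, srate, labels = NULL, start_time = 0, meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite samples")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("`labels` length (", length(labels), ") must equal channel count (",
         nrow(data), ")")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  rownames(data) <- labels
  structure(
    list(data = data, srate = srate, labels = labels,
         start_time = start_time, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$data), ncol(x$data), x$srate, n_samples(x) / x$srate))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a [recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Sample times of a recording
#' @param rec a [recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  rec$start_time + (seq_len(n_samples(rec)) - 1L) / rec$srate
}

#' Extract channels from a recording
#' @param rec a [recording()].
#' @param channels character vector of channel labels to keep, in order.
#' @return A [recording()] restricted to `channels`.
#' @export
pick_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$labels)
  if (length(missing))
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  recording(rec$data[channels, , drop = FALSE], rec$srate, channels,
            rec$start_time, rec$meta)
}

#' Drop channels from a recording
#' @param rec a [recording()].
#' @param channels labels to remove (channels absent from the recording are
#'   ignored, so one exclusion list can serve several montages).
#' @return A [recording()] without `channels`.
#' @export
drop_channels <- function(rec, channels) {
  keep <- setdiff(rec$labels, channels)
  if (!length(keep)) stop("dropping all channels leaves an empty recording")
  pick_channels(rec, keep)
}

#' Write / read a recording as columnar CSV
#'
#' The on-disk layout is one `time` column (seconds) followed by one column per
#' channel (microvolts); the sampling rate is recovered from the time column on
#' read.
#'
#' @param rec a [recording()].
#' @param path file path.
#' @return `write_recording_csv` returns `path` invisibly; `read_recording_csv`
#'   returns a [recording()].
#' @export
write_recording_csv <- function(rec, path) {
  df <- data.frame(time = sample_times(rec), t(rec$data), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("recording CSV must contain a `time` column")
  tt <- df$time
  srate <- 1 / stats::median(diff(tt))
  dat <- t(as.matrix(df[setdiff(names(df), "time")]))
  recording(dat, srate = srate, labels = rownames(dat), start_time = tt[1])
}

#' Write / read event markers as CSV
#'
#' Events are stored as `(sample_index, label)` rows; `sample_index` is 1-based.
#'
#' @param events data.frame with columns `sample_index`, `label`.
#' @param path file path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv` the
#'   data.frame.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(all(c("sample_index", "label") %in% names(events)))
  utils::write.csv(events[c("sample_index", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
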