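#' Trial schedule for rest / ready / imagery epochs
#'
#' Builds the per-trial timing table of a feedback or evaluation block. Each
#' trial is a resting epoch, a ready epoch, and a motor-imagery epoch played
#' back-to-back; trials are separated by an inter-trial interval during which
#' participants may move freely.
#'
#' @param n_trials number of trials.
#' @param rest_dur resting-epoch duration in seconds (default 6).
#' @param ready_dur ready-epoch duration in seconds (default 1).
#' @param imagery_dur motor-imagery epoch duration in seconds (default 5).
#' @param iti inter-trial interval in seconds appended after each imagery epoch
#'   (default 8: score display plus free interval).
#' @param start time of the first rest onset in seconds (default 0).
#'
#' @return A `trial_schedule`: data.frame with columns `trial`, `rest_onset`,
#'   `ready_onset`, `imagery_onset`, `imagery_end` (seconds), plus attributes
#'   `iti` and epoch durations.
#' @export
#' @examples
#' sched <- trial_schedule(3)
#' schedule_duration(sched)
trial_schedule <- function(n_trials, rest_dur = 6, ready_dur = 1,
                           imagery_dur = 5, iti = 8, start = 0) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (any(c(rest_dur, ready_dur, imagery_dur) <= 0) || iti < 0)
    stop("epoch durations must be positive and `iti` non-negative")
  trial_len <- rest_dur + ready_dur + imagery_dur
  rest_onset <- start + (seq_len(n_trials) - 1L) * (trial_len + iti)
  out <- data.frame(
    trial = seq_len(n_trials),
    rest_onset = rest_onset,
    ready_onset = rest_onset + rest_dur,
    imagery_onset = rest_onset + rest_dur + ready_dur,
    imagery_end = rest_onset + trial_len
  )
  structure(out, class = c("trial_schedule", "data.frame"),
            iti = iti, rest_dur = rest_dur, ready_dur = ready_dur,
            imagery_dur = imagery_dur)
}

#' Validate a trial schedule
#'
#' Checks strict ordering within each trial and non-overlap between successive
#' trials. Called by consumers before epoching.
#'
#' @param sched a [trial_schedule()] or compatible data.frame.
#' @return `sched`, invisibly; throws on violation.
#' @export
validate_schedule <- function(sched) {
  need <- c("rest_onset", "ready_onset", "imagery_onset", "imagery_end")
  if (!all(need %in% names(sched)))
    stop("schedule must contain columns: ", paste(need, collapse = ", "))
  m <- as.matrix(sched[need])
  if (any(m[, -1] <= m[, -4]))
    stop("epoch onsets must be strictly increasing within each trial")
  if (nrow(sched) > 1 &&
      any(sched$rest_onset[-1] < sched$imagery_end[-nrow(sched)]))
    stop("trials overlap: a rest onset precedes the previous imagery end")
  invisible(sched)
}

#' Total span of a schedule
#' @param sched a [trial_schedule()].
#' @return Last imagery end time, in seconds.
#' @export
schedule_duration <- function(sched) max(sched$imagery_end)

#' Write / read a trial schedule as CSV
#' @param sched a [trial_schedule()].
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   the validated schedule.
#' @export
write_schedule_csv <- function(sched, path) {
  utils::write.csv(as.data.frame(sched), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  sched <- utils::read.csv(path)
  validate_schedule(sched)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}
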