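#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given order forward and
#' backward (zero-phase), removing baseline wander below `low_hz` and
#' sensor noise above `high_hz` while leaving fiducial timing
#' undistorted. Zero-phase filtering is used because the downstream
#' features include foot-to-peak and peak-to-peak times, which a causal
#' filter's group delay would bias; the effective magnitude response is
#' the squared single-pass response.
#'
#' @param record A [ppg_record].
#' @param low_hz Lower cutoff in Hz (default 1).
#' @param high_hz Upper cutoff in Hz (default 5).
#' @param order Filter order of the underlying low/high-pass prototypes
#'   (default 2, i.e. a 2nd-order band-pass design).
#' @return A [ppg_record] of the same length with the filtered samples.
#' @export
bandpass <- function(record, low_hz = 1, high_hz = 5, order = 2) {
  stopifnot(inherits(record, "ppg_record"))
  nyq <- record$fs_hz / 2
  if (low_hz <= 0 || low_hz >= high_hz) {
    abort_invalid_parameter("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    abort_invalid_parameter(sprintf(
      "upper cutoff %g Hz must be below the Nyquist frequency %g Hz", high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- as.numeric(signal::filtfilt(bf, record$samples))
  ppg_record(y, record$fs_hz, t0_s = record$t0_s, channel = record$channel)
}

#' Trim the filter transient
#'
#' Drops the first `trim_s` seconds of a record, discarding the filter
#' settling segment; a 70-s window becomes the 60-s analysis segment.
#'
#' @param record A [ppg_record].
#' @param trim_s Seconds to remove from the start (default 10).
#' @return The trimmed [ppg_record].
#' @export
trim_transient <- function(record, trim_s = 10) {
  stopifnot(inherits(record, "ppg_record"))
  if (duration_s(record) <= trim_s) {
    abort_insufficient_data(sprintf(
      "record (%.1f s) is not longer than the %g-s transient trim",
      duration_s(record), trim_s))
  }
  n_drop <- round(trim_s * record$fs_hz)
  ppg_record(record$samples[(n_drop + 1L):length(record$samples)],
             record$fs_hz, t0_s = record$t0_s + trim_s, channel = record$channel)
}

#' Default automatic artifact detector
#'
#' A reproducible stand-in for visual artifact screening: a candidate
#' window is flagged if any 1-s segment's amplitude range exceeds 5x the
#' window's median per-second range (burst), or falls below 1% of it
#' (flat-line / sensor dropout).
#'
#' @param record A [ppg_record] holding one candidate window.
#' @return `TRUE` if the window is artifact-free.
#' @export
default_artifact_detector <- function(record) {
  fs <- record$fs_hz
  n_sec <- floor(duration_s(record))
  if (n_sec < 2) return(TRUE)
  rng <- vapply(seq_len(n_sec), function(k) {
    seg <- record$samples[(round((k - 1) * fs) + 1L):min(round(k * fs), length(record$samples))]
    diff(range(seg))
  }, numeric(1))
  med <- stats::median(rng)
  if (med == 0) return(FALSE)
  all(rng <= 5 * med & rng >= 0.01 * med)
}

#' Select the analysis window preceding the pressure measurement
#'
#' Picks the 70-s window ending at the wedge-pressure measurement time.
#' If the artifact detector rejects it, the window start is advanced
#' (moved earlier) in `step_s` steps up to `max_advance_s` before the
#' nominal start, mirroring the practice of re-selecting a clean segment
#' before an artifactual one. If no candidate passes, the least
#' artifacted candidate is returned with `artifact_flagged = TRUE`.
#'
#' @param record A [ppg_record] covering the candidate windows.
#' @param pcwp_time_s Pressure measurement time, seconds on the record's
#'   time axis. Defaults to the end of the record.
#' @param artifact_detector Predicate `function(ppg_record) -> logical`;
#'   `NULL` disables screening. Default [default_artifact_detector()].
#' @param window_s Window length in seconds (default 70).
#' @param step_s Search step in seconds (default 10).
#' @param max_advance_s Maximum total advance in seconds (default 300,
#'   i.e. 5 minutes).
#' @return A list: `record` (the 70-s slice) and `selection`, a
#'   `window_selection` with `start_s`, `end_s`, `advanced_by_s`,
#'   `artifact_flagged`.
#' @export
select_window <- function(record, pcwp_time_s = NULL,
                          artifact_detector = default_artifact_detector,
                          window_s = 70, step_s = 10, max_advance_s = 300) {
  stopifnot(inherits(record, "ppg_record"))
  if (is.null(pcwp_time_s)) pcwp_time_s <- record$t0_s + duration_s(record)
  if (duration_s(record) < window_s) {
    abort_insufficient_data(sprintf(
      "record (%.1f s) is shorter than the %g-s analysis window",
      duration_s(record), window_s))
  }
  advances <- seq(0, max_advance_s, by = step_s)
  # candidates must lie inside the record
  advances <- advances[pcwp_time_s - advances - window_s >= record$t0_s - 1e-9]
  if (!length(advances)) {
    abort_insufficient_data("no candidate window fits inside the record")
  }
  score_best <- Inf; best <- NULL; best_adv <- NA_real_
  for (adv in advances) {
    end_s <- pcwp_time_s - adv
    cand <- slice_record(record, end_s - window_s, end_s)
    if (is.null(artifact_detector)) {
      return(list(record = cand,
                  selection = window_selection(end_s - window_s, end_s, adv, FALSE)))
    }
    if (isTRUE(artifact_detector(cand))) {
      return(list(record = cand,
                  selection = window_selection(end_s - window_s, end_s, adv, FALSE)))
    }
    sc <- artifact_severity(cand)
    if (sc < score_best) {
      score_best <- sc; best <- cand; best_adv <- adv
    }
  }
  list(record = best,
       selection = window_selection(best$t0_s, best$t0_s + window_s, best_adv, TRUE))
}

window_selection <- function(start_s, end_s, advanced_by_s, artifact_flagged) {
  structure(
    list(start_s = start_s, end_s = end_s, advanced_by_s = advanced_by_s,
         artifact_flagged = artifact_flagged),
    class = "window_selection"
  )
}

# severity used only to rank candidates when all are flagged: worst
# per-second range ratio against the median
artifact_severity <- function(record) {
  fs <- record$fs_hz
  n_sec <- floor(duration_s(record))
  rng <- vapply(seq_len(n_sec), function(k) {
    seg <- record$samples[(round((k - 1) * fs) + 1L):min(round(k * fs), length(record$samples))]
    diff(range(seg))
  }, numeric(1))
  med <- stats::median(rng)
  if (med == 0) return(Inf)
  max(rng / med)
}

#' Preprocess one record end to end
#'
#' Window selection, zero-phase band-pass, transient trim: the standard
#' chain that turns a raw recording into the 60-s analysis segment.
#'
#' @inheritParams select_window
#' @inheritParams bandpass
#' @inheritParams trim_transient
#' @return A list: `record` (the filtered, trimmed analysis segment) and
#'   `selection` (the `window_selection` used).
#' @export
preprocess_record <- function(record, pcwp_time_s = NULL,
                              artifact_detector = default_artifact_detector,
                              window_s = 70, step_s = 10, max_advance_s = 300,
                              low_hz = 1, high_hz = 5, order = 2, trim_s = 10) {
  win <- select_window(record, pcwp_time_s, artifact_detector,
                       window_s = window_s, step_s = step_s,
                       max_advance_s = max_advance_s)
  filt <- bandpass(win$record, low_hz = low_hz, high_hz = high_hz, order = order)
  list(record = trim_transient(filt, trim_s = trim_s), selection = win$selection)
}
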