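#' Construct a PPG record
#'
#' A `ppg_record` is a uniformly sampled single-channel
#' photoplethysmography waveform: an amplitude vector (arbitrary units),
#' a sampling rate in Hz, a start time in seconds, and a channel label.
#'
#' @param samples Numeric vector of amplitudes (dimensionless device units).
#' @param fs_hz Sampling rate in Hz. Wrist wearables of the kind this
#'   package targets stream a green-light channel at 128 Hz.
#' @param t0_s Recording start time in seconds (default 0). All window
#'   arithmetic in the package is in seconds relative to this origin.
#' @param channel Channel label, e.g. `"green-525nm"`.
#'
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs_hz, t0_s = 0, channel = "green-525nm") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || !is.finite(fs_hz) || fs_hz <= 0) {
    abort_invalid_parameter("`fs_hz` must be a single positive number")
  }
  if (length(samples) < 2L) {
    abort_insufficient_data("a `ppg_record` needs at least 2 samples")
  }
  structure(
    list(samples = samples, fs_hz = as.numeric(fs_hz),
         t0_s = as.numeric(t0_s), channel = as.character(channel)),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %d samples @ %g Hz (%.1f s), t0 = %g s, channel %s\n",
              length(x$samples), x$fs_hz, duration_s(x), x$t0_s, x$channel))
  invisible(x)
}

#' @export
length.ppg_record <- function(x) length(x$samples)

duration_s <- function(record) length(record$samples) / record$fs_hz

# Time axis of a record, seconds, 0-based sample indexing: sample i
# (0-based) sits at t0_s + i / fs_hz.
record_times <- function(record) {
  record$t0_s + (seq_along(record$samples) - 1L) / record$fs_hz
}

# Half-open slice [from_s, to_s) in absolute seconds.
slice_record <- function(record, from_s, to_s) {
  i0 <- ceiling((from_s - record$t0_s) * record$fs_hz - 1e-9)
  i1 <- ceiling((to_s - record$t0_s) * record$fs_hz - 1e-9)
  i0 <- max(i0, 0)
  i1 <- min(i1, length(record$samples))
  if (i1 - i0 < 2) {
    abort_insufficient_data("requested slice contains fewer than 2 samples")
  }
  ppg_record(record$samples[(i0 + 1L):i1], record$fs_hz,
             t0_s = record$t0_s + i0 / record$fs_hz, channel = record$channel)
}

#' Read a waveform CSV
#'
#' The interchange format is a two-column CSV (`time_s`, `amplitude`)
#' with one sample per row and uniform sampling. The sampling rate is
#' inferred from the median time step unless given.
#'
#' @param path Path to the CSV file.
#' @param fs_hz Optional sampling rate override in Hz.
#' @param channel Channel label to attach.
#' @return A [ppg_record].
#' @export
read_waveform_csv <- function(path, fs_hz = NULL, channel = "green-525nm") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    abort_invalid_parameter(sprintf(
      "waveform CSV %s must have columns time_s, amplitude", path))
  }
  if (nrow(df) < 2L) abort_insufficient_data("waveform CSV has fewer than 2 samples")
  if (is.null(fs_hz)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) {
      abort_invalid_parameter("cannot infer sampling rate from time_s column")
    }
    fs_hz <- 1 / dt
    # snap to an integer rate when within float noise of one (128, 64, ...)
    if (abs(fs_hz - round(fs_hz)) < 1e-6) fs_hz <- round(fs_hz)
  }
  ppg_record(df$amplitude, fs_hz, t0_s = df$time_s[1], channel = channel)
}

#' Write a waveform CSV
#'
#' Inverse of [read_waveform_csv()]; amplitudes are written at full
#' precision (15 significant digits) so a write-read round trip is
#' lossless to numerical tolerance.
#'
#' @param record A [ppg_record].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  df <- data.frame(
    time_s = format(record_times(record), digits = 15, trim = TRUE, scientific = FALSE),
    amplitude = format(record$samples, digits = 15, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
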