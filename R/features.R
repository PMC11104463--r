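#' Extract the six pulse-wave features
#'
#' Per-beat values are computed from the fiducial positions and
#' aggregated across quality-passing beats:
#' \describe{
#'   \item{SA}{systolic amplitude, signal at the systolic peak minus
#'     signal at the foot;}
#'   \item{DA}{diastolic amplitude, signal at the diastolic peak minus
#'     signal at the foot;}
#'   \item{CT}{crest time, foot-to-systolic-peak time in seconds;}
#'   \item{LASI}{large artery stiffness index, the reciprocal of the
#'     systolic-to-diastolic peak delay in 1/s (a stiffer arterial tree
#'     reflects earlier, giving a shorter delay and a larger index; the
#'     delay itself is reported as `delta_t_s`);}
#'   \item{HR}{60 / mean inter-beat interval, from successive systolic
#'     peaks;}
#'   \item{HRV}{SDNN (default) or RMSSD of the inter-beat intervals, in
#'     seconds.}
#' }
#' SA/DA/CT/LASI are aggregated with the median (default) for robustness
#' to residual artifacts; timing uses sub-sample fiducial positions.
#' When no beat has a diastolic fiducial, DA and LASI are `NA` and
#' downstream models exclude the subject for those features only.
#'
#' @param beats Data frame from [locate_foot_and_diastolic()].
#' @param x A [ppg_record] or numeric vector (the same signal the beats
#'   were located on).
#' @param fs_hz Sampling rate in Hz (ignored when `x` is a record).
#' @param aggregation `"median"` (default) or `"mean"` across beats.
#' @param hrv_metric `"sdnn"` (default) or `"rmssd"`.
#' @return An object of class `feature_set`: a list with `hr_bpm`,
#'   `hrv_s`, `sa`, `da`, `ct_s`, `lasi_inv_s`, plus `delta_t_s`,
#'   `n_beats`, `n_beats_quality`.
#' @export
extract_features <- function(beats, x, fs_hz = NULL,
                             aggregation = c("median", "mean"),
                             hrv_metric = c("sdnn", "rmssd")) {
  aggregation <- match.arg(aggregation)
  hrv_metric <- match.arg(hrv_metric)
  y <- if (inherits(x, "ppg_record")) x$samples else as.numeric(x)
  if (inherits(x, "ppg_record")) fs_hz <- x$fs_hz
  if (is.null(fs_hz) || fs_hz <= 0) abort_invalid_parameter("`fs_hz` required")
  ok <- beats[beats$quality_ok, , drop = FALSE]
  if (nrow(ok) < 2L) {
    abort_insufficient_beats("fewer than 2 quality-passing beats")
  }
  agg <- if (aggregation == "median") stats::median else mean

  sa_k <- y[ok$sys_peak_idx] - y[ok$foot_idx]
  ct_k <- (ok$sys_pos - ok$foot_pos) / fs_hz
  has_dia <- !is.na(ok$dia_peak_idx)
  da_k <- ifelse(has_dia, y[ok$dia_peak_idx] - y[ok$foot_idx], NA_real_)
  dt_k <- ifelse(has_dia, (ok$dia_pos - ok$sys_pos) / fs_hz, NA_real_)

  # rhythm from all detected systolic peaks (quality gating concerns
  # morphology, not timing)
  ibis <- diff(sort(unique(beats$sys_pos))) / fs_hz
  if (length(ibis) < 1L) abort_insufficient_beats("cannot form inter-beat intervals")
  hr <- 60 / mean(ibis)
  hrv <- if (hrv_metric == "sdnn") {
    stats::sd(ibis)
  } else {
    sqrt(mean(diff(ibis)^2))
  }
  if (length(ibis) == 1L) hrv <- 0

  dt <- if (any(has_dia)) agg(dt_k[has_dia]) else NA_real_
  structure(
    list(
      hr_bpm = hr,
      hrv_s = hrv,
      sa = agg(sa_k),
      da = if (any(has_dia)) agg(da_k[has_dia]) else NA_real_,
      ct_s = agg(ct_k),
      lasi_inv_s = if (!is.na(dt) && dt > 0) 1 / dt else NA_real_,
      delta_t_s = dt,
      n_beats = nrow(beats),
      n_beats_quality = nrow(ok)
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> HR %.1f bpm, HRV %.3f s, SA %.3g, DA %.3g, CT %.3f s, LASI %.2f 1/s (%d/%d beats)\n",
    x$hr_bpm, x$hrv_s, x$sa, if (is.na(x$da)) NA else x$da, x$ct_s,
    if (is.na(x$lasi_inv_s)) NA else x$lasi_inv_s, x$n_beats_quality, x$n_beats))
  invisible(x)
}

#' Full feature extraction from a filtered analysis segment
#'
#' Convenience chain: [detect_systolic_peaks()] then
#' [locate_foot_and_diastolic()] then [extract_features()].
#'
#' @param record A filtered [ppg_record] (the 60-s analysis segment).
#' @inheritParams extract_features
#' @inheritParams detect_systolic_peaks
#' @return A `feature_set`.
#' @export
ppg_features <- function(record, aggregation = c("median", "mean"),
                         hrv_metric = c("sdnn", "rmssd"),
                         min_separation_s = 0.33, min_prominence_frac = 0.3) {
  pk <- detect_systolic_peaks(record, min_separation_s = min_separation_s,
                              min_prominence_frac = min_prominence_frac)
  beats <- locate_foot_and_diastolic(record, pk)
  extract_features(beats, record, aggregation = aggregation,
                   hrv_metric = hrv_metric)
}

feature_names <- function() c("hr_bpm", "hrv_s", "sa", "da", "ct_s", "lasi_inv_s")

#' Feature table for a cohort of recordings
#'
#' Runs the preprocessing and feature chain over every subject of a
#' rendered synthetic cohort (or any list with `record` and `pcwp_mmHg`
#' entries) and returns the per-subject feature table.
#'
#' @param cohort A `ppg_cohort` from [generate_cohort()].
#' @param ... Passed to [preprocess_record()] and [ppg_features()].
#' @return A data frame: `subject_id`, the six features, `delta_t_s`,
#'   `n_beats`, `n_beats_quality`, `pcwp_mmHg`, `pcwp_class`, `af_flag`.
#' @export
cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  args <- list(...)
  pre_names <- intersect(names(args), names(formals(preprocess_record)))
  feat_names <- intersect(names(args), names(formals(ppg_features)))
  rows <- lapply(cohort, function(s) {
    if (is.null(s$record)) abort_invalid_parameter("cohort was not rendered")
    pre <- do.call(preprocess_record, c(list(s$record), args[pre_names]))
    fs <- do.call(ppg_features, c(list(pre$record), args[feat_names]))
    data.frame(subject_id = s$subject_id, hr_bpm = fs$hr_bpm, hrv_s = fs$hrv_s,
               sa = fs$sa, da = fs$da, ct_s = fs$ct_s,
               lasi_inv_s = fs$lasi_inv_s, delta_t_s = fs$delta_t_s,
               n_beats = fs$n_beats, n_beats_quality = fs$n_beats_quality,
               pcwp_mmHg = s$pcwp_mmHg, pcwp_class = s$pcwp_class,
               af_flag = s$af, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
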