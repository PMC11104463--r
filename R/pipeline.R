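#' Pipeline configuration
#'
#' One nested list holding every tunable numeric used anywhere in the
#' pipeline, with the defaults of the reference analysis: 2nd-order
#' Butterworth band-pass at 1-5 Hz, a 70-s window trimmed to 60 s with at
#' most 300 s of advance in 10-s steps, SDNN heart-rate variability with
#' median beat aggregation, 3-fold stratified cross-validation with equal
#' priors and a 12-mmHg class threshold, and a 0.05 family alpha over the
#' three morphology comparisons.
#'
#' @param ... Named overrides of the form `filter = list(low_hz = 0.5)`;
#'   unnamed sections keep their defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = list(low_hz = 1, high_hz = 5, order = 2),
    window = list(length_s = 70, trim_s = 10, max_advance_s = 300, step_s = 10),
    features = list(hrv_metric = "sdnn", aggregation = "median",
                    min_separation_s = 0.33, min_prominence_frac = 0.3),
    models = list(n_folds = 3, seed = 1, stratified = TRUE, priors = "equal",
                  threshold_mmHg = 12),
    stats = list(family_alpha = 0.05,
                 family = c("sa", "lasi_inv_s", "ct_s"))
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) abort_invalid_parameter(sprintf("unknown config section `%s`", nm))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are config
#'   sections (`filter`, `window`, `features`, `models`, `stats`).
#' @return A [pipeline_config()] with the file's overrides applied.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline over a cohort manifest
#'
#' For every manifest row: read the waveform, select the analysis window
#' preceding the pressure measurement, band-pass filter, trim the
#' transient, extract the six pulse-wave features; then fit the
#' cross-validated single-feature regression and classification models
#' and the between-class comparisons. Subjects whose waveform cannot be
#' read or yields too few beats are excluded with the reason logged;
#' fewer than 6 usable subjects aborts.
#'
#' @param manifest_path Path to a manifest CSV with columns
#'   `subject_id`, `waveform_path` (relative paths resolved against the
#'   manifest's directory), `pcwp_mmHg`, and optionally `af_flag` and
#'   `pcwp_time_s`.
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `results.csv`, `comparisons.csv`, and `run_log.json`.
#' @return A list: `features` (per-subject table), `results` (model
#'   metrics), `comparisons` (group tests), `exclusions`, `config`.
#' @export
run_pipeline <- function(manifest_path, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "waveform_path", "pcwp_mmHg")
  if (!all(need %in% names(manifest))) {
    abort_invalid_parameter(sprintf(
      "manifest must have columns %s", paste(need, collapse = ", ")))
  }
  base_dir <- dirname(manifest_path)
  exclusions <- list()
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    wf <- manifest$waveform_path[i]
    if (!file.exists(wf)) wf <- file.path(base_dir, manifest$waveform_path[i])
    res <- tryCatch({
      rec <- read_waveform_csv(wf)
      pcwp_time <- if ("pcwp_time_s" %in% names(manifest) &&
                       is.finite(manifest$pcwp_time_s[i])) {
        manifest$pcwp_time_s[i]
      } else {
        NULL
      }
      pre <- preprocess_record(
        rec, pcwp_time_s = pcwp_time,
        window_s = config$window$length_s, step_s = config$window$step_s,
        max_advance_s = config$window$max_advance_s,
        low_hz = config$filter$low_hz, high_hz = config$filter$high_hz,
        order = config$filter$order, trim_s = config$window$trim_s)
      fs <- ppg_features(
        pre$record, aggregation = config$features$aggregation,
        hrv_metric = config$features$hrv_metric,
        min_separation_s = config$features$min_separation_s,
        min_prominence_frac = config$features$min_prominence_frac)
      data.frame(subject_id = sid, hr_bpm = fs$hr_bpm, hrv_s = fs$hrv_s,
                 sa = fs$sa, da = fs$da, ct_s = fs$ct_s,
                 lasi_inv_s = fs$lasi_inv_s, delta_t_s = fs$delta_t_s,
                 n_beats = fs$n_beats, n_beats_quality = fs$n_beats_quality,
                 pcwp_mmHg = manifest$pcwp_mmHg[i],
                 artifact_flagged = pre$selection$artifact_flagged,
                 advanced_by_s = pre$selection$advanced_by_s,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[sid]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) < 6L) {
    abort_pw(sprintf("only %d usable subjects (need >= 6)", length(rows)),
             "pulsewedge_insufficient_cohort")
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  records <- subject_records(features, threshold_mmHg = config$models$threshold_mmHg)
  results <- evaluate_features(records, seed = config$models$seed,
                               n_folds = config$models$n_folds)
  comparisons <- compare_features(records,
                                  feature_names = config$stats$family,
                                  family_alpha = config$stats$family_alpha)
  bundle <- list(features = records, results = results,
                 comparisons = comparisons, exclusions = exclusions,
                 config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
    log <- list(
      manifest = normalizePath(manifest_path),
      n_subjects_in = nrow(manifest), n_subjects_used = nrow(records),
      exclusions = exclusions, config = unclass(config),
      config_hash = config_hash(config)
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

config_hash <- function(config) {
  # dependency-free stable digest: serialize to canonical JSON, then sum
  # a simple polynomial rolling hash of the bytes
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%d", h)
}
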