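#' Build subject records from a feature table
#'
#' Attaches the pressure class at the clinical threshold: subjects with
#' wedge pressure >= `threshold_mmHg` are `"high"`, the rest `"low"`.
#'
#' @param features Data frame with one row per subject, the feature
#'   columns, and `pcwp_mmHg`.
#' @param threshold_mmHg Class threshold in mmHg (default 12, the upper
#'   limit of a physiologically normal wedge pressure).
#' @return The same data frame with a `pcwp_class` factor column.
#' @export
subject_records <- function(features, threshold_mmHg = 12) {
  stopifnot(is.data.frame(features), "pcwp_mmHg" %in% names(features))
  features$pcwp_class <- factor(ifelse(features$pcwp_mmHg >= threshold_mmHg,
                                       "high", "low"),
                                levels = c("low", "high"))
  features
}

# fold assignment 1..k; optionally stratified so each fold gets a
# near-equal share of every stratum
make_folds <- function(n, k, seed, strata = NULL) {
  with_seed(seed, {
    folds <- integer(n)
    if (is.null(strata)) {
      folds <- sample(rep_len(seq_len(k), n))
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    }
    folds
  })
}

#' ROC curve and AUC
#'
#' Operating points over all score thresholds; the area under the curve
#' is computed by the trapezoidal rule and equals the normalised
#' Mann-Whitney U statistic of the scores between classes, with tied
#' scores handled by the midpoint (average rank) convention.
#'
#' @param scores Numeric vector (larger = more likely positive).
#' @param labels Logical/0-1/factor vector; `TRUE`/1/second level =
#'   positive class.
#' @return A list: `fpr`, `tpr` (operating points, thresholds descending),
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  if (!any(pos) || all(pos)) {
    abort_invalid_parameter("both classes must be present to form a ROC curve")
  }
  if (length(scores) != length(pos)) {
    abort_invalid_parameter("`scores` and `labels` lengths differ")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single operating points
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  # trapezoid; identical to (wins + ties/2) / (n1*n0) via average ranks
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  r <- rank(scores)  # average ranks: midpoint tie convention
  n1 <- sum(pos); n0 <- sum(!pos)
  auc_rank <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(fpr = fpr, tpr = tpr, auc = auc_rank, auc_trapezoid = auc_trap)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.numeric(labels)) return(labels > 0)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (length(lv) > 2) abort_invalid_parameter("more than two label values")
    # "high"/"low" orientation: high is positive
    if (setequal(lv, c("high", "low"))) return(labels == "high")
    return(labels == lv[2])
  }
  abort_invalid_parameter("unsupported label type")
}

#' Cross-validated single-feature linear regression
#'
#' Ordinary least squares of the continuous wedge pressure on one
#' feature, fitted per training fold; out-of-fold predictions are pooled
#' and scored once: R^2 = 1 - SS_res / SS_tot with SS_tot about the
#' full-sample mean. Under this pooled out-of-fold convention an
#' uninformative feature typically scores *below* zero, because the
#' per-fold fits chase noise while the reference mean does not.
#'
#' @param records Data frame from [subject_records()] (needs the feature
#'   column and `pcwp_mmHg`).
#' @param feature_name Name of the feature column.
#' @param seed Integer seed for the fold assignment.
#' @param n_folds Number of folds (default 3).
#' @return An `eval_result` list: `feature_name`, `task`, `metric_name`
#'   (`"r2_oof"`), `metric_value`, `fold_assignments`, `oof_predictions`,
#'   `n_used`, `seed`.
#' @export
crossval_regression <- function(records, feature_name, seed = 1L, n_folds = 3L) {
  x <- records[[feature_name]]
  if (is.null(x)) abort_invalid_parameter(sprintf("no feature column `%s`", feature_name))
  keep <- is.finite(x) & is.finite(records$pcwp_mmHg)
  d <- records[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 2L * n_folds) {
    abort_insufficient_data(sprintf(
      "%d usable subjects for `%s`; need at least %d for %d-fold regression",
      n, feature_name, 2L * n_folds, n_folds))
  }
  if (stats::sd(d[[feature_name]]) == 0) {
    abort_degenerate(sprintf("feature `%s` is constant", feature_name))
  }
  folds <- make_folds(n, n_folds, seed)
  oof <- rep(NA_real_, n)
  for (k in seq_len(n_folds)) {
    tr <- d[folds != k, , drop = FALSE]
    te <- d[folds == k, , drop = FALSE]
    if (nrow(tr) < 2L) abort_insufficient_data("a training fold has fewer than 2 subjects")
    fit <- stats::lm(stats::reformulate(feature_name, "pcwp_mmHg"), data = tr)
    oof[folds == k] <- stats::predict(fit, newdata = te)
  }
  ss_res <- sum((d$pcwp_mmHg - oof)^2)
  ss_tot <- sum((d$pcwp_mmHg - mean(d$pcwp_mmHg))^2)
  eval_result(feature_name, "regression", "r2_oof", 1 - ss_res / ss_tot,
              folds, oof, d$subject_id, n, seed)
}

#' Cross-validated single-feature linear discriminant classification
#'
#' Two-class LDA on one feature — class-conditional normals with pooled
#' within-class variance and (by default) equal priors — fitted per
#' training fold. Fold assignment is stratified by class so every
#' training fold contains both classes. Out-of-fold discriminant scores
#' are expressed as the posterior probability of the high class, so
#' scores pooled across folds share one orientation; the pooled scores
#' give a single ROC and its AUC.
#'
#' @param records Data frame from [subject_records()].
#' @param feature_name Name of the feature column.
#' @param seed Integer seed for the stratified fold assignment.
#' @param n_folds Number of folds (default 3).
#' @param priors `"equal"` (default) or `"empirical"` class priors.
#' @param stratified Stratify folds by class (default TRUE).
#' @return An `eval_result` list with `metric_name = "auc_oof"` and the
#'   pooled ROC under `roc`.
#' @export
crossval_lda <- function(records, feature_name, seed = 1L, n_folds = 3L,
                         priors = c("equal", "empirical"), stratified = TRUE) {
  priors <- match.arg(priors)
  x <- records[[feature_name]]
  if (is.null(x)) abort_invalid_parameter(sprintf("no feature column `%s`", feature_name))
  if (is.null(records$pcwp_class)) records <- subject_records(records)
  keep <- is.finite(x)
  d <- records[keep, , drop = FALSE]
  cls <- d$pcwp_class
  if (min(table(cls)) < n_folds) {
    abort_insufficient_data(sprintf(
      "need at least %d subjects per class for stratified %d-fold LDA",
      n_folds, n_folds))
  }
  folds <- make_folds(nrow(d), n_folds, seed,
                      strata = if (stratified) cls else NULL)
  oof <- rep(NA_real_, nrow(d))
  for (k in seq_len(n_folds)) {
    tr_i <- folds != k
    tr_x <- d[[feature_name]][tr_i]; tr_c <- cls[tr_i]
    if (length(unique(tr_c)) < 2L) {
      abort_pw("a training fold lost a class", "pulsewedge_stratification")
    }
    fit <- lda1_fit(tr_x, tr_c == "high", priors)
    oof[folds == k] <- lda1_posterior(fit, d[[feature_name]][folds == k])
  }
  roc <- roc_curve(oof, cls == "high")
  res <- eval_result(feature_name, "classification", "auc_oof", roc$auc,
                     folds, oof, d$subject_id, nrow(d), seed)
  res$roc <- roc
  res
}

# one-dimensional two-class LDA: pooled within-class variance
lda1_fit <- function(x, positive, priors = "equal") {
  x1 <- x[positive]; x0 <- x[!positive]
  n1 <- length(x1); n0 <- length(x0)
  v1 <- if (n1 > 1) stats::var(x1) else 0
  v0 <- if (n0 > 1) stats::var(x0) else 0
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  if (!is.finite(s2) || s2 <= 0) {
    abort_degenerate("zero pooled within-class variance; LDA fit is degenerate")
  }
  m1 <- mean(x1); m0 <- mean(x0)
  log_prior <- if (priors == "empirical") log(n1 / n0) else 0
  list(w = (m1 - m0) / s2,
       b = -(m1^2 - m0^2) / (2 * s2) + log_prior)
}

# posterior probability of the positive (high) class
lda1_posterior <- function(fit, x) {
  stats::plogis(fit$w * x + fit$b)
}

eval_result <- function(feature_name, task, metric_name, metric_value,
                        folds, oof, subject_ids, n_used, seed) {
  names(folds) <- subject_ids
  names(oof) <- subject_ids
  structure(
    list(feature_name = feature_name, task = task, metric_name = metric_name,
         metric_value = metric_value, fold_assignments = folds,
         oof_predictions = oof, n_used = n_used, seed = seed),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s / %s: %s = %.4f (n = %d, seed = %d)\n",
              x$feature_name, x$task, x$metric_name, x$metric_value,
              x$n_used, x$seed))
  invisible(x)
}

#' Evaluate every feature with both model families
#'
#' Runs [crossval_regression()] and [crossval_lda()] for each feature and
#' collects the pooled out-of-fold metrics. Features whose models cannot
#' be fitted (missing in too many subjects, constant, ...) are reported
#' with `NA` and the reason.
#'
#' @param records Data frame from [subject_records()].
#' @param feature_names Character vector of feature columns (default the
#'   six pulse-wave features).
#' @param seed Integer seed.
#' @param n_folds Number of folds (default 3).
#' @return A data frame: `feature`, `task`, `metric_name`,
#'   `metric_value`, `n_used`, `fold_seed`, `note`.
#' @export
evaluate_features <- function(records, feature_names = NULL, seed = 1L,
                              n_folds = 3L) {
  if (is.null(feature_names)) {
    feature_names <- intersect(c("hr_bpm", "hrv_s", "sa", "da", "ct_s", "lasi_inv_s"),
                               names(records))
  }
  rows <- list()
  for (f in feature_names) {
    for (task in c("regression", "classification")) {
      res <- tryCatch({
        if (task == "regression") {
          crossval_regression(records, f, seed = seed, n_folds = n_folds)
        } else {
          crossval_lda(records, f, seed = seed, n_folds = n_folds)
        }
      }, pulsewedge_error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "eval_result")) {
        data.frame(feature = f, task = task, metric_name = res$metric_name,
                   metric_value = res$metric_value, n_used = res$n_used,
                   fold_seed = seed, note = "", stringsAsFactors = FALSE)
      } else {
        data.frame(feature = f, task = task,
                   metric_name = if (task == "regression") "r2_oof" else "auc_oof",
                   metric_value = NA_real_, n_used = 0L, fold_seed = seed,
                   note = conditionMessage(res), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
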