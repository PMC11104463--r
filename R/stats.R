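#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. The U statistic is
#' computed from average ranks (midpoint tie convention) and the smaller
#' of the two mirrored statistics is reported. The two-sided p-value is
#' exact (full enumeration of rank assignments) when the smaller group
#' has at most `exact_max` observations and there are no ties, and uses
#' the normal approximation with tie-corrected variance otherwise.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param exact_max Largest `min(n_a, n_b)` for which the exact null
#'   distribution is used (default 8).
#' @return A list: `u` (min-U), `u_a` (U for `group_a`), `p`
#'   (two-sided), `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 8) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (!length(a) || !length(b)) {
    abort_invalid_parameter("both groups must be non-empty")
  }
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_b <- na * nb - u_a
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(na, nb) <= exact_max
  p <- stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  list(u = min(u_a, u_b), u_a = u_a, p = p, n_a = na, n_b = nb,
       exact = use_exact)
}

#' Bonferroni-corrected significance level
#'
#' Divides the family-wise significance level by the number of
#' comparisons; reported rounded to 4 decimals, matching the convention
#' of printing e.g. 0.05 / 3 = 0.0167.
#'
#' @param family_alpha Family-wise alpha in (0, 1) (default 0.05).
#' @param n_tests Number of comparisons in the family (>= 1).
#' @return The corrected per-test alpha.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests) {
  if (missing(n_tests) || n_tests < 1) {
    abort_invalid_parameter("`n_tests` must be >= 1")
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    abort_invalid_parameter("`family_alpha` must be in (0, 1)")
  }
  round(family_alpha / n_tests, 4)
}

#' Compare features between pressure classes
#'
#' Mann-Whitney U test of each feature between the low and high wedge
#' pressure classes, with the Bonferroni-corrected significance level.
#' The comparison family defaults to the three morphology features
#' (systolic amplitude, stiffness index, crest time); the family size
#' sets the corrected alpha.
#'
#' @param records Data frame from [subject_records()].
#' @param feature_names Features in the comparison family (default
#'   `c("sa", "lasi_inv_s", "ct_s")`).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return A data frame: `feature`, `n_low`, `n_high`, `U`, `p`,
#'   `alpha_corrected`, `significant`.
#' @export
compare_features <- function(records, feature_names = c("sa", "lasi_inv_s", "ct_s"),
                             family_alpha = 0.05) {
  if (is.null(records$pcwp_class)) records <- subject_records(records)
  alpha <- bonferroni_alpha(family_alpha, length(feature_names))
  rows <- lapply(feature_names, function(f) {
    x <- records[[f]]
    if (is.null(x)) abort_invalid_parameter(sprintf("no feature column `%s`", f))
    lo <- x[records$pcwp_class == "low" & is.finite(x)]
    hi <- x[records$pcwp_class == "high" & is.finite(x)]
    mw <- mann_whitney_u(lo, hi)
    data.frame(feature = f, n_low = length(lo), n_high = length(hi),
               U = mw$u, p = mw$p, alpha_corrected = alpha,
               significant = mw$p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
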