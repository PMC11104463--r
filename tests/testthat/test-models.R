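test_that("roc_curve reproduces hand-computable cases", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # positives rank 1st and 3rd: one win of four pairs
  expect_equal(roc_curve(c(1, 2, 3, 4), c(1, 0, 1, 0))$auc, 0.25)
  expect_equal(roc_curve(rep(2, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)),
               class = "pulsewedge_invalid_parameter")
})

test_that("roc_curve operating points and both area computations agree", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, brute_force_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc_trapezoid, r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
  }
})

test_that("roc_curve agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(40)
  labels <- sample(c(0, 1), 40, replace = TRUE)
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

make_gt_records <- function(n = 14, effect = 0, seed = 1) {
  co <- generate_cohort(cohort_spec(n_subjects = n, effect_size = effect,
                                    seed = seed), render = FALSE)
  subject_records(cohort_ground_truth(co))
}

test_that("regression attains R2 = 1 on an exact linear relationship", {
  rec <- make_gt_records(n = 15, seed = 3)
  rec$pcwp_mmHg <- 4 + 2.5 * rec$sa
  res <- crossval_regression(rec, "sa", seed = 1)
  expect_equal(res$metric_value, 1, tolerance = 1e-9)
  expect_equal(sort(unique(res$fold_assignments)), 1:3)
  expect_length(res$oof_predictions, 15)
})

test_that("regression guards its preconditions", {
  rec <- make_gt_records(n = 15, seed = 3)
  expect_error(crossval_regression(rec[1:5, ], "sa", seed = 1),
               class = "pulsewedge_insufficient_data")
  rec$flat <- 1
  expect_error(crossval_regression(rec, "flat", seed = 1),
               class = "pulsewedge_degenerate")
  expect_error(crossval_regression(rec, "no_such", seed = 1),
               class = "pulsewedge_invalid_parameter")
})

test_that("uninformative features produce negative pooled out-of-fold R2", {
  r2 <- vapply(1:60, function(sd) {
    crossval_regression(make_gt_records(seed = sd), "sa", seed = sd)$metric_value
  }, numeric(1))
  expect_lt(stats::median(r2), 0)
})

test_that("LDA separates perfectly separable classes and respects symmetry", {
  rec <- make_gt_records(n = 14, seed = 5)
  # construct perfect separation: all high-class values below all low
  rec$sep <- ifelse(rec$pcwp_class == "high", rnorm(14, 0, 0.1),
                    rnorm(14, 10, 0.1))
  res <- crossval_lda(rec, "sep", seed = 2)
  expect_equal(res$metric_value, 1)
  # scoring the pooled predictions against inverted labels gives the
  # complementary area; refitting is label-symmetric by construction
  inv <- roc_curve(res$oof_predictions,
                   rec$pcwp_class[match(names(res$oof_predictions),
                                        rec$subject_id)] == "low")$auc
  expect_equal(inv, 1 - res$metric_value)
})

test_that("LDA classification is invariant to monotone feature transforms", {
  rec <- make_gt_records(n = 20, effect = 1.5, seed = 9)
  a1 <- crossval_lda(rec, "sa", seed = 4)$metric_value
  rec$sa <- exp(3 * rec$sa)
  a2 <- crossval_lda(rec, "sa", seed = 4)$metric_value
  expect_equal(a1, a2, tolerance = 0.15)
})

test_that("stratified folds keep both classes in every training fold", {
  rec <- make_gt_records(n = 14, seed = 7)
  res <- crossval_lda(rec, "sa", seed = 3)
  folds <- res$fold_assignments
  cls <- rec$pcwp_class[match(names(folds), rec$subject_id)]
  for (k in 1:3) {
    expect_equal(length(unique(cls[folds != k])), 2L)
  }
  expect_length(folds, 14)
  expect_true(all(table(folds) >= 4))
})

test_that("the in-package discriminant matches the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- c(rnorm(10, 0), rnorm(8, 1.2))
  g <- rep(c(FALSE, TRUE), c(10, 8))
  fit <- pulsewedge:::lda1_fit(x, g, priors = "equal")
  ours <- pulsewedge:::lda1_posterior(fit, x)
  ref <- MASS::lda(data.frame(x = x), grouping = g, prior = c(0.5, 0.5))
  post <- predict(ref, data.frame(x = x))$posterior[, "TRUE"]
  expect_equal(ours, unname(post), tolerance = 1e-8)
})

test_that("LDA guards degenerate inputs", {
  rec <- make_gt_records(n = 14, seed = 11)
  rec$flat <- 1
  expect_error(crossval_lda(rec, "flat", seed = 1),
               class = "pulsewedge_degenerate")
  expect_error(crossval_lda(rec[1:5, ], "sa", seed = 1),
               class = "pulsewedge_insufficient_data")
})

test_that("evaluate_features reports all feature-task pairs with metrics", {
  rec <- make_gt_records(n = 14, effect = 2, seed = 13)
  res <- evaluate_features(rec, seed = 5)
  expect_equal(nrow(res), 12)
  expect_setequal(unique(res$task), c("regression", "classification"))
  auc <- res$metric_value[res$task == "classification"]
  expect_true(all(auc >= 0 & auc <= 1, na.rm = TRUE))
})
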