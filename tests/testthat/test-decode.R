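test_that("leave-one-out produces one fold per subject", {
  co <- strong_cohort(seed = 42)
  cv <- loocv_decode(co)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$folds), 26L)
  expect_setequal(cv$folds$subject, co$table$id)
  expect_equal(cv$folds$true, as.character(co$labels))
  # deterministic: same inputs, same result
  cv2 <- loocv_decode(co)
  expect_identical(cv$folds, cv2$folds)
  expect_error(loocv_decode(co$maps[1:3, ], co$labels[1:3]),
               "two subjects per class")
})

test_that("contradictorily labeled duplicates are uninformative", {
  # the same feature vector appears once per class: a model trained on all
  # subjects cannot separate the pair and predicts it near chance
  set.seed(8)
  X <- matrix(rnorm(10 * 5), 10, 5)
  X[10, ] <- X[1, ]  # same features, opposite labels
  y <- factor(rep(c("normal", "chronic"), each = 5),
              levels = c("normal", "chronic"))
  fit <- slr_fit(X, y)
  expect_lt(abs(predict_proba(fit, X[1, ]) - 0.5), 0.35)
  # under leave-one-out the held-out copy is pulled toward its twin's
  # label, so the two folds give complementary predictions
  cv <- loocv_decode(X, y)
  expect_lt(abs(cv$folds$prob[1] + cv$folds$prob[10] - 1), 0.35)
})

test_that("fold accuracies are exchangeable under joint permutation", {
  co <- strong_cohort(seed = 9, n_per_group = 5)
  cv <- loocv_decode(co)
  set.seed(1)
  perm <- sample(nrow(co$maps))
  cvp <- loocv_decode(co$maps[perm, ], co$labels[perm])
  correct <- cv$folds$predicted == cv$folds$true
  correctp <- cvp$folds$predicted == cvp$folds$true
  expect_equal(sort(correct), sort(correctp))
  expect_equal(correct[perm], correctp)
})

test_that("performance metrics reproduce the 12/13-correct benchmark", {
  # 12 of 13 correct in each group: every rate is 92.3%
  folds <- data.frame(
    subject = sprintf("s%02d", 1:26),
    true = rep(c("chronic", "normal"), each = 13),
    predicted = c(rep("chronic", 12), "normal",
                  rep("normal", 12), "chronic"),
    prob = rep(0.5, 26), n_selected = 3L, converged = TRUE)
  cv <- structure(list(folds = folds, selected = rep(list(1:3), 26),
                       labels = factor(folds$true,
                                       levels = c("normal", "chronic")),
                       n_features = 10L),
                  class = "cv_result")
  perf <- performance_metrics(cv)
  expect_equal(perf$accuracy, 12 / 13)
  expect_equal(perf$sensitivity, 12 / 13)
  expect_equal(perf$specificity, 12 / 13)
  expect_equal(perf$ppv, 12 / 13)
  expect_equal(perf$npv, 12 / 13)
  expect_equal(100 * perf$accuracy, 92.3, tolerance = 1e-3)
  # d' from the standard inverse-normal transform
  expect_equal(perf$d_prime, 2 * qnorm(12 / 13), tolerance = 1e-10)
  expect_equal(perf$d_prime, 2.852, tolerance = 1e-3)
  # confusion-matrix conservation
  cm <- perf$confusion
  expect_equal(unname(cm["tp"] + cm["tn"]), perf$accuracy * 26)
  expect_equal(perf$sensitivity * 13 + perf$specificity * 13,
               perf$accuracy * 26)
})

test_that("d-prime is zero at chance and guarded at extremes", {
  folds <- data.frame(
    subject = sprintf("s%02d", 1:8),
    true = rep(c("chronic", "normal"), each = 4),
    predicted = c("chronic", "chronic", "normal", "normal",
                  "normal", "normal", "chronic", "chronic"),
    prob = 0.5, n_selected = 0L, converged = TRUE)
  cv <- structure(list(folds = folds, selected = rep(list(integer(0)), 8),
                       labels = factor(folds$true,
                                       levels = c("normal", "chronic")),
                       n_features = 2L),
                  class = "cv_result")
  perf <- performance_metrics(cv)
  expect_equal(perf$d_prime, 0)
  # perfect separation: the 1/(2N) rule keeps d' finite
  folds$predicted <- folds$true
  cv$folds <- folds
  perfp <- performance_metrics(cv)
  expect_true(is.finite(perfp$d_prime))
  expect_equal(perfp$d_prime, 2 * qnorm(1 - 1 / 8), tolerance = 1e-10)
})

test_that("beta posterior summaries are analytic", {
  # k = n = 26: Beta(27, 1)
  p <- beta_posterior_accuracy(26, 26)
  expect_equal(p$mean, 27 / 28)
  expect_equal(p$upper, qbeta(0.975, 27, 1))
  # no data: uniform prior
  p0 <- beta_posterior_accuracy(0, 0)
  expect_equal(p0$mean, 0.5)
  expect_equal(c(p0$lower, p0$upper), c(0.025, 0.975))
  # interval width shrinks as n grows at fixed k/n
  widths <- vapply(c(26, 104, 416), function(n) {
    b <- beta_posterior_accuracy(round(24 / 26 * n), n)
    b$upper - b$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(beta_posterior_accuracy(5, 3))
})

test_that("permutation p-values use the add-one estimator", {
  # very strong planted effects: the observed accuracy tops every null draw
  m <- tiny_mask()
  tr <- ground_truth(c(2L, 9L, 15L), c(-6, -6, 6), seed = 77)
  co <- simulate_contrast_cohort(m, tr, 13)
  pt <- permutation_test_accuracy(co, B = 19, seed = 5,
                                  keep_selection = FALSE)
  expect_equal(pt$p_value,
               (1 + sum(pt$null_values >= pt$observed)) / (19 + 1))
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  # deterministic under the same seed
  pt2 <- permutation_test_accuracy(co, B = 19, seed = 5,
                                   keep_selection = FALSE)
  expect_identical(pt$null_values, pt2$null_values)
  expect_equal(pt$observed, 1)
  expect_true(all(pt$null_values < 1))
  expect_equal(pt$p_value, 1 / 20)
})

test_that("permutation p-values are valid at several alpha levels", {
  # small null cohorts so the full permutation machinery stays cheap
  m <- tiny_mask()
  pvals <- vapply(1:40, function(k) {
    co <- simulate_contrast_cohort(m, ground_truth(integer(0), 0,
                                                   seed = 60000L + k), 4)
    permutation_test_accuracy(co, B = 19, seed = 61000L + k,
                              keep_selection = FALSE)$p_value
  }, numeric(1))
  mc_tol <- 3 * sqrt(0.1 * 0.9 / 40)  # ~0.14
  for (a in c(0.01, 0.05, 0.1))
    expect_lte(mean(pvals <= a), a + mc_tol)
})

test_that("selection-count significance flags planted voxels only", {
  co <- strong_cohort(seed = 101)
  pt <- permutation_test_accuracy(co, B = 30, seed = 11)
  fs <- feature_selection_significance(pt$cv, pt, q = 0.05)
  idx <- co$truth$informative_indices
  # the most-selected informative voxel attains the smallest p-value in
  # the table (folds share 24 of 25 subjects, so permuted-label decoders
  # also select *some* voxel consistently; the null count distribution is
  # therefore long-tailed and count-based flags are conservative)
  top_inf <- idx[which.max(fs$table$count[idx])]
  expect_equal(fs$table$p[top_inf], min(fs$table$p))
  expect_lt(fs$table$p[top_inf], 0.01)
  # flags are monotone in count whenever anything is flagged
  if (any(fs$table$flag)) {
    thr <- min(fs$table$count[fs$table$flag])
    expect_true(all(fs$table$flag[fs$table$count >= thr]))
  }
  # all-zero observed counts yield nothing significant
  cv0 <- pt$cv
  cv0$selected <- rep(list(integer(0)), length(cv0$selected))
  fs0 <- feature_selection_significance(cv0, pt, q = 0.05)
  expect_false(any(fs0$table$flag))
  # max-statistic mode is at least as conservative as the pooled mode
  fsm <- feature_selection_significance(pt$cv, pt, q = 0.05,
                                        method = "max")
  expect_true(all(fsm$table$p >= fs$table$p - 1e-12))
  expect_error(feature_selection_significance(pt$cv, NULL), "permutation")
})
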