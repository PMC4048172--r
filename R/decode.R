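#' Leave-one-out cross-validation of the sparse decoder
#'
#' Trains one classifier per subject on the remaining subjects and tests it
#' on the held-out one, so every subject is predicted exactly once by a
#' model that never saw it. Standardization (when enabled in `hyper`) is
#' computed on each training fold only and applied to the held-out subject.
#'
#' @param maps Subjects x features matrix, or a `contrast_cohort`.
#' @param labels Two-level factor (ignored when `maps` is a cohort unless
#'   supplied explicitly); second level is the positive class.
#' @param hyper An [slr_hyper()].
#' @return Object of class `cv_result`: `folds` data frame (subject, true,
#'   predicted, prob, n_selected, converged), `selected` (list of retained
#'   feature indices per fold), `labels`, `n_features`.
#' @export
loocv_decode <- function(maps, labels = NULL, hyper = slr_hyper()) {
  if (inherits(maps, "contrast_cohort")) {
    if (is.null(labels)) labels <- maps$labels
    maps <- maps$maps
  }
  maps <- as.matrix(maps)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, nrow(maps) == length(labels))
  if (any(table(labels) < 2L))
    stop("need at least two subjects per class for leave-one-out")
  n <- nrow(maps)
  ids <- rownames(maps) %||% sprintf("s%02d", seq_len(n))
  prob <- numeric(n)
  pred <- character(n)
  conv <- logical(n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      slr_fit(maps[-i, , drop = FALSE], labels[-i], hyper))
    prob[i] <- predict_proba(fit, maps[i, ])
    pred[i] <- predict_label(fit, maps[i, ])
    conv[i] <- fit$converged
    selected[[i]] <- fit$retained
  }
  folds <- data.frame(subject = ids, true = as.character(labels),
                      predicted = pred, prob = prob,
                      n_selected = lengths(selected), converged = conv,
                      stringsAsFactors = FALSE)
  structure(list(folds = folds, selected = selected, labels = labels,
                 n_features = ncol(maps)),
            class = "cv_result")
}

#' Classification performance of a cross-validation result
#'
#' Accuracy, sensitivity, specificity, predictive values, discriminability
#' (d'), the mean retained-feature count, and the beta-posterior summary of
#' accuracy. For d', rates of exactly 0 or 1 are moved by `1/(2N)` (N the
#' group size) before the inverse-normal transform.
#'
#' @param cv A [loocv_decode()] result.
#' @param positive_class Label treated as positive (default: the second
#'   factor level, i.e. "chronic" for the standard cohort).
#' @param adjust_extreme_rates Apply the 1/(2N) rule to degenerate rates in
#'   d' (default TRUE); with FALSE, degenerate rates yield infinite d'.
#' @return Object of class `performance_report`.
#' @export
performance_metrics <- function(cv, positive_class = levels(cv$labels)[2L],
                                adjust_extreme_rates = TRUE) {
  stopifnot(inherits(cv, "cv_result"))
  truth <- cv$folds$true == positive_class
  pred <- cv$folds$predicted == positive_class
  P <- sum(truth); N <- sum(!truth)
  stopifnot(P > 0, N > 0)
  tp <- sum(truth & pred);  fn <- P - tp
  tn <- sum(!truth & !pred); fp <- N - tn
  acc <- (tp + tn) / (P + N)
  sens <- tp / P
  spec <- tn / N
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  hr <- sens; far <- 1 - spec
  if (adjust_extreme_rates) {
    hr <- min(max(hr, 1 / (2 * P)), 1 - 1 / (2 * P))
    far <- min(max(far, 1 / (2 * N)), 1 - 1 / (2 * N))
  }
  dprime <- qnorm(hr) - qnorm(far)
  post <- beta_posterior_accuracy(tp + tn, P + N)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, d_prime = dprime,
                 posterior_mean = post$mean,
                 posterior_interval = c(post$lower, post$upper),
                 mean_n_features = mean(cv$folds$n_selected),
                 confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
                 positive_class = positive_class),
            class = "performance_report")
}

#' Beta-posterior summary of classification accuracy
#'
#' Under a uniform Beta(1, 1) prior on the correct-classification
#' probability and `k` correct out of `n`, the posterior is
#' Beta(1 + k, 1 + n - k); reported are its mean and the central credible
#' interval (a posterior probability interval serving as a confidence
#' interval).
#'
#' @param k Number of correct classifications.
#' @param n Total classifications.
#' @param level Credible level (default 0.95).
#' @return List with `mean`, `lower`, `upper`.
#' @export
beta_posterior_accuracy <- function(k, n, level = 0.95) {
  stopifnot(k >= 0, n >= 0, k <= n, level > 0, level < 1)
  a <- 1 + k; b <- 1 + n - k
  half <- (1 - level) / 2
  list(mean = a / (a + b),
       lower = qbeta(half, a, b),
       upper = qbeta(1 - half, a, b))
}

#' Permutation test of decoding accuracy
#'
#' Reruns the full leave-one-out cross-validation on `B` random relabelings
#' of the subjects (group sizes preserved) and compares the observed
#' accuracy to the null accuracies. The p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (B + 1)`.
#'
#' @param maps Subjects x features matrix or `contrast_cohort`.
#' @param labels Labels (see [loocv_decode()]).
#' @param hyper An [slr_hyper()].
#' @param B Number of permutations.
#' @param seed Integer seed; per-permutation sub-seeds are derived from it.
#' @param keep_selection Record per-voxel selection counts of each permuted
#'   rerun (needed by [feature_selection_significance()]).
#' @return Object of class `permutation_null`: `observed`, `null_values`,
#'   `p_value`, `B`, `cv` (the observed CV result) and, when requested,
#'   `perm_selection_counts` (features x B).
#' @export
permutation_test_accuracy <- function(maps, labels = NULL,
                                      hyper = slr_hyper(), B = 1000L,
                                      seed = 1L, keep_selection = TRUE) {
  if (inherits(maps, "contrast_cohort")) {
    if (is.null(labels)) labels <- maps$labels
    maps <- maps$maps
  }
  stopifnot(B >= 1)
  labels <- as.factor(labels)
  cv <- loocv_decode(maps, labels, hyper)
  observed <- mean(cv$folds$predicted == cv$folds$true)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  null_values <- numeric(B)
  counts <- if (keep_selection)
    matrix(0L, ncol(maps), B) else NULL
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    perm <- sample(labels)
    cvb <- loocv_decode(maps, perm, hyper)
    null_values[b] <- mean(cvb$folds$predicted == cvb$folds$true)
    if (keep_selection)
      counts[, b] <- tabulate(unlist(cvb$selected), nbins = ncol(maps))
  }
  p <- (1 + sum(null_values >= observed)) / (B + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, B = as.integer(B), cv = cv,
                 perm_selection_counts = counts),
            class = "permutation_null")
}

#' Permutation significance of per-voxel selection counts
#'
#' For each voxel, the number of cross-validation folds in which it was
#' selected is compared with the distribution of selection counts under
#' permuted labels. Two null constructions are available: `"pooled"` pools
#' counts across voxels and permutations (then applies Benjamini-Hochberg
#' FDR at `q`), `"max"` uses the per-permutation maximum count across voxels
#' (a family-wise-error construction; flags are `p <= q` directly).
#'
#' @param cv A [loocv_decode()] result run on the true labels.
#' @param perm_counts Features x permutations matrix of selection counts
#'   from permuted reruns (see [permutation_test_accuracy()]), or a
#'   `permutation_null` carrying one.
#' @param q FDR level (or FWER level for `method = "max"`).
#' @param method `"pooled"` (default) or `"max"`.
#' @return Object of class `feature_significance`: data frame with `voxel`,
#'   `count`, `p`, `flag`, plus the null description.
#' @export
feature_selection_significance <- function(cv, perm_counts, q = 0.05,
                                           method = c("pooled", "max")) {
  stopifnot(inherits(cv, "cv_result"))
  method <- match.arg(method)
  if (inherits(perm_counts, "permutation_null"))
    perm_counts <- perm_counts$perm_selection_counts
  if (is.null(perm_counts) || NCOL(perm_counts) < 1L)
    stop("at least one permutation is required")
  perm_counts <- as.matrix(perm_counts)
  if (nrow(perm_counts) != cv$n_features)
    stop("perm_counts rows must match the number of features")
  obs <- tabulate(unlist(cv$selected), nbins = cv$n_features)
  if (method == "pooled") {
    null_counts <- as.integer(perm_counts)
    m <- length(null_counts)
    # P(null >= c) with add-one correction, via the null's upper tail
    tail_ge <- function(cnt) (1 + sum(null_counts >= cnt)) / (m + 1)
    p <- vapply(obs, tail_ge, numeric(1L))
    flag <- p.adjust(p, method = "BH") <= q
  } else {
    maxima <- apply(perm_counts, 2L, max)
    B <- length(maxima)
    p <- vapply(obs, function(cnt) (1 + sum(maxima >= cnt)) / (B + 1),
                numeric(1L))
    flag <- p <= q
  }
  structure(list(table = data.frame(voxel = seq_along(obs), count = obs,
                                    p = p, flag = flag),
                 q = q, method = method,
                 n_permutations = ncol(perm_counts)),
            class = "feature_significance")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Decoder performance (positive class:", x$positive_class, ")\n")
  cat(sprintf("  accuracy     %5.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  sensitivity  %5.1f%%   specificity %5.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  PPV          %5.1f%%   NPV         %5.1f%%\n",
              100 * x$ppv, 100 * x$npv))
  cat(sprintf("  d'           %6.3f\n", x$d_prime))
  cat(sprintf("  posterior accuracy %.1f%% [%.1f%%, %.1f%%]\n",
              100 * x$posterior_mean, 100 * x$posterior_interval[1L],
              100 * x$posterior_interval[2L]))
  cat(sprintf("  mean retained features %.2f\n", x$mean_n_features))
  invisible(x)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed accuracy %.3f, B = %d, p = %.4f\n",
    x$observed, x$B, x$p_value))
  invisible(x)
}
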