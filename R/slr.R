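#' Hyperparameters for sparse ARD logistic regression
#'
#' The decoder places independent zero-mean Gaussian priors on the feature
#' weights whose precisions (the ARD parameters) are re-estimated from the
#' data by MacKay evidence updates; features whose precision diverges are
#' pruned, so feature selection happens during fitting.
#'
#' @param alpha_init Initial ARD precision shared by all features.
#' @param prune_threshold Precision above which a feature is removed from the
#'   model. Pruned features never re-enter.
#' @param max_iter Maximum number of outer (ARD update) iterations.
#' @param tol Relative change in the full weight vector below which the outer
#'   loop is declared converged.
#' @param standardize If `TRUE` (default) features are z-scored with training
#'   statistics before fitting; test data must be transformed with the same
#'   statistics (handled by [predict_proba()]).
#' @param max_newton Maximum Newton-Raphson steps per MAP subproblem.
#' @param newton_tol Convergence tolerance of the Newton subproblem.
#' @param bias_precision Fixed prior precision of the intercept; broad so the
#'   intercept is effectively unpenalized, and never pruned.
#'
#' @return An object of class `slr_hyper`.
#' @export
slr_hyper <- function(alpha_init = 1.0, prune_threshold = 1e8,
                      max_iter = 500L, tol = 1e-6, standardize = TRUE,
                      max_newton = 50L, newton_tol = 1e-8,
                      bias_precision = 1e-10) {
  stopifnot(alpha_init > 0, prune_threshold > alpha_init, max_iter >= 1,
            tol > 0, max_newton >= 1, newton_tol > 0, bias_precision > 0)
  structure(list(alpha_init = alpha_init, prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol,
                 standardize = isTRUE(standardize),
                 max_newton = as.integer(max_newton),
                 newton_tol = newton_tol, bias_precision = bias_precision),
            class = "slr_hyper")
}

#' Fit a sparse logistic-regression classifier with ARD
#'
#' Trains the decoder: a Bayesian logistic regression whose per-feature prior
#' precisions are re-estimated by evidence (MacKay) updates under a Laplace
#' approximation of the posterior. Most precisions diverge, so only a few
#' relevant features survive -- simultaneous feature selection and weight
#' estimation.
#'
#' @param x Numeric matrix, subjects in rows, features (voxels) in columns.
#' @param y Binary labels: a two-level factor (second level is class 1), a
#'   logical, or a 0/1 numeric vector.
#' @param hyper An [slr_hyper()] object.
#'
#' @return An object of class `slr_model` with elements `retained` (1-based
#'   indices of surviving features), `w`, `bias`, `alpha`, `center`/`scale`
#'   (training standardization for the retained features), `n_features`,
#'   `n_iter`, `converged`.
#' @export
slr_fit <- function(x, y, hyper = slr_hyper()) {
  x <- as.matrix(x)
  y01 <- encode_labels(y)
  if (nrow(x) != length(y01))
    stop("number of rows of `x` must match length of `y`")
  if (length(unique(y01)) < 2L)
    stop("`y` must contain both classes")
  p <- ncol(x)

  center <- colMeans(x)
  xc <- x - rep(center, each = nrow(x))
  scl2 <- colSums(xc^2) / (nrow(x) - 1L)
  keep <- is.finite(scl2) & scl2 > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped before fitting")
  if (hyper$standardize) {
    scl <- sqrt(scl2)
    xs <- xc[, keep, drop = FALSE] / rep(scl[keep], each = nrow(x))
  } else {
    center <- rep(0, p)
    scl <- rep(1, p)
    xs <- x[, keep, drop = FALSE]
  }

  fit <- slr_ard_fit_cpp(xs, as.numeric(y01), hyper$alpha_init,
                         hyper$prune_threshold, hyper$max_iter, hyper$tol,
                         hyper$bias_precision, hyper$max_newton,
                         hyper$newton_tol)
  idx_kept <- which(keep)
  retained <- idx_kept[fit$retained + 1L]
  structure(list(retained = retained,
                 w = as.numeric(fit$w),
                 bias = fit$bias,
                 alpha = as.numeric(fit$alpha),
                 center = center[retained],
                 scale = scl[retained],
                 standardize = hyper$standardize,
                 n_features = p,
                 levels = attr(y01, "levels"),
                 n_iter = fit$n_iter,
                 converged = fit$converged),
            class = "slr_model")
}

# map labels to 0/1; second factor level (or TRUE, or 1) is class 1
encode_labels <- function(y) {
  if (is.factor(y) || is.character(y)) {
    f <- as.factor(y)
    if (nlevels(f) != 2L) stop("`y` must have exactly two levels")
    out <- as.integer(f) - 1L
    attr(out, "levels") <- levels(f)
    return(out)
  }
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("numeric `y` must be coded 0/1")
  out <- as.integer(y)
  attr(out, "levels") <- c("0", "1")
  out
}

#' Predicted class-1 probability
#'
#' Applies the training standardization to the new observation(s) and returns
#' the logistic response over the retained features.
#'
#' @param model An [slr_fit()] result.
#' @param x Numeric vector of length `n_features`, or a matrix with that many
#'   columns.
#' @return Probability (or vector of probabilities) of class 1, in (0, 1).
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "slr_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_features)
    stop("feature-count mismatch: model has ", model$n_features,
         " features, input has ", ncol(x))
  xr <- x[, model$retained, drop = FALSE]
  if (model$standardize && length(model$retained))
    xr <- sweep(sweep(xr, 2L, model$center, "-"), 2L, model$scale, "/")
  eta <- model$bias + as.numeric(xr %*% model$w)
  as.numeric(1 / (1 + exp(-eta)))
}

#' Predicted class label
#'
#' Class 1 if the predicted probability exceeds 0.5. A probability of exactly
#' 0.5 is assigned to class 0 (for chronic-pain decoding with labels
#' normal/chronic this is the "normal" class) -- an arbitrary but fixed rule.
#'
#' @inheritParams predict_proba
#' @return Character label(s) drawn from the training levels.
#' @export
predict_label <- function(model, x) {
  p <- predict_proba(model, x)
  model$levels[ifelse(p > 0.5, 2L, 1L)]
}

#' MAP weights of the logistic model at fixed prior precisions
#'
#' The inner Newton-Raphson subproblem of the ARD loop, exposed directly:
#' maximizes the logistic log-likelihood minus the quadratic penalty
#' \eqn{\frac12 \sum_i \alpha_i w_i^2} at fixed \eqn{\alpha}.
#'
#' @param x Feature matrix (used as-is; no standardization).
#' @param y Binary labels as in [slr_fit()].
#' @param alpha Vector of prior precisions, one per column of `x`.
#' @param bias_precision Prior precision of the intercept.
#' @return List with `w` and `bias`.
#' @export
slr_map_weights <- function(x, y, alpha, bias_precision = 1e-10) {
  x <- as.matrix(x)
  y01 <- encode_labels(y)
  stopifnot(length(alpha) == ncol(x), all(alpha > 0))
  fit <- slr_map_fixed_alpha_cpp(x, as.numeric(y01), as.numeric(alpha),
                                 bias_precision, 200L, 1e-12)
  list(w = as.numeric(fit$w), bias = fit$bias)
}

#' @export
print.slr_model <- function(x, ...) {
  cat("Sparse ARD logistic regression model\n")
  cat(sprintf("  features: %d total, %d retained\n",
              x$n_features, length(x$retained)))
  if (length(x$retained))
    cat("  retained indices:", paste(x$retained, collapse = ", "), "\n")
  cat(sprintf("  bias: %.4f; iterations: %d; converged: %s\n",
              x$bias, x$n_iter, x$converged))
  invisible(x)
}
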