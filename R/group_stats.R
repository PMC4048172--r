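#' Voxelwise two-sample t-map
#'
#' Pooled-variance between-subjects t statistic at every mask voxel (group A
#' minus group B), with two-sided p-values and Benjamini-Hochberg FDR flags.
#' Voxels with zero pooled variance are masked out with a warning.
#'
#' @param maps_a,maps_b Subjects x voxels matrices for the two groups.
#' @param mask Optional `mask_volume` used to attach mm coordinates.
#' @param q FDR level for the suprathreshold flags.
#' @return Object of class `tmap`: `t`, `p`, `dof`, `flags`,
#'   `fdr_threshold`, and a `peaks` table of FDR-significant voxels
#'   (with MNI coordinates when a mask is given).
#' @export
two_sample_tmap <- function(maps_a, maps_b, mask = NULL, q = 0.05) {
  A <- as.matrix(maps_a); B <- as.matrix(maps_b)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2L, nrow(B) >= 2L)
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2L, m1)^2); v2 <- colSums(sweep(B, 2L, m2)^2)
  dof <- n1 + n2 - 2L
  sp2 <- (v1 + v2) / dof
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  if (any(bad <- !is.finite(t))) {
    warning(sum(bad), " voxel(s) with zero pooled variance masked out")
    t[bad] <- NA_real_
  }
  p <- 2 * pt(-abs(t), dof)
  finalize_tmap(t, p, dof, mask, q)
}

finalize_tmap <- function(t, p, dof, mask, q) {
  fdr <- fdr_threshold(p[!is.na(p)], q)
  flags <- !is.na(p) & p <= (fdr$threshold %||% -1)
  peaks <- data.frame(voxel = which(flags), t = t[flags], p = p[flags])
  if (!is.null(mask) && nrow(peaks)) {
    mm <- mask$coords_mm[peaks$voxel, , drop = FALSE]
    peaks$x_mm <- mm[, 1L]; peaks$y_mm <- mm[, 2L]; peaks$z_mm <- mm[, 3L]
  }
  structure(list(t = t, p = p, dof = dof, q = q, flags = flags,
                 fdr_threshold = fdr$threshold, peaks = peaks, mask = mask),
            class = "tmap")
}

#' Benjamini-Hochberg FDR threshold and flags
#'
#' Step-up rule: with ordered p-values `p_(1) <= ... <= p_(m)`, the
#' threshold is the largest `p_(i)` with `p_(i) <= i q / m`; every p-value
#' at or below it is flagged.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `threshold` (NULL if nothing passes) and logical
#'   `flags` in the input order.
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  adj <- p.adjust(p_values, method = "BH")
  flags <- !is.na(adj) & adj <= q
  thr <- if (any(flags)) max(p_values[flags]) else NULL
  list(threshold = thr, flags = flags)
}

#' Threshold-weighted two-sample t-map
#'
#' Scales each subject's contrast map by that subject's pain-threshold
#' level (mA) before the between-groups t-test, probing whether group
#' differences are explained by stimulation intensity.
#'
#' @param maps Subjects x voxels matrix.
#' @param weights Positive per-subject weights (pain thresholds).
#' @param groups Two-level factor; the first level is group A.
#' @inheritParams two_sample_tmap
#' @return A `tmap`.
#' @export
weighted_contrast_tmap <- function(maps, weights, groups, mask = NULL,
                                   q = 0.05) {
  maps <- as.matrix(maps)
  groups <- as.factor(groups)
  if (length(weights) != nrow(maps) || anyNA(weights))
    stop("need one non-missing weight per subject")
  stopifnot(all(weights > 0), nlevels(groups) == 2L)
  w <- maps * weights
  two_sample_tmap(w[groups == levels(groups)[1L], , drop = FALSE],
                  w[groups == levels(groups)[2L], , drop = FALSE],
                  mask = mask, q = q)
}

#' Voxelwise correlation with chronic-pain duration
#'
#' Pearson correlation of each voxel's contrast value with years since
#' onset, converted to a t statistic with `n - 2` degrees of freedom.
#' A perfect correlation yields the largest representable t.
#'
#' @param maps_chronic Chronic-group subjects x voxels matrix.
#' @param durations Years since onset, one per subject.
#' @inheritParams two_sample_tmap
#' @return A `tmap` (t from r, two-sided p, plus `r` per voxel).
#' @export
duration_correlation_map <- function(maps_chronic, durations, mask = NULL,
                                     q = 0.05) {
  X <- as.matrix(maps_chronic)
  n <- nrow(X)
  stopifnot(length(durations) == n, n >= 3L)
  if (sd(durations) == 0) stop("durations are constant")
  r <- as.numeric(cor(durations, X))
  dof <- n - 2L
  t <- r * sqrt(dof / pmax(1 - r^2, 0))
  t[!is.finite(t)] <- sign(r[!is.finite(t)]) * sqrt(.Machine$double.xmax)
  p <- 2 * pt(-abs(t), dof)
  out <- finalize_tmap(t, p, dof, mask, q)
  out$r <- r
  out
}

#' Small-volume correction within a spherical region of interest
#'
#' Restricts the FDR correction of a t-map to the mask voxels within
#' `radius` mm of a center coordinate.
#'
#' @param tmap A [two_sample_tmap()]-style result carrying its mask.
#' @param center MNI mm coordinate of the sphere center.
#' @param radius Search radius in mm (default 8).
#' @param q FDR level.
#' @return List with `voxels` (mask-voxel indices in the sphere), `p`,
#'   `flags`, `threshold`.
#' @export
small_volume_correction <- function(tmap, center, radius = 8, q = 0.05) {
  stopifnot(inherits(tmap, "tmap"))
  if (is.null(tmap$mask))
    stop("the t-map carries no mask; coordinates are unavailable")
  d2 <- colSums((t(tmap$mask$coords_mm) - center)^2)
  vox <- which(d2 <= radius^2 & !is.na(tmap$p))
  if (length(vox) == 0L)
    stop("the sphere does not intersect the mask")
  fdr <- fdr_threshold(tmap$p[vox], q)
  list(voxels = vox, p = tmap$p[vox], flags = fdr$flags,
       threshold = fdr$threshold)
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by full enumeration of group assignments when the
#' combined sample size is at most 12 (mid-ranks for ties); otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined n for the exact path.
#' @return List with `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(rk[combs], nrow = n1))
    muW <- n1 * (n + 1) / 2
    p <- mean(abs(sums - muW) >= abs(W - muW) - 1e-9)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  muW <- n1 * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigW <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- (W - muW - sign(W - muW) * 0.5) / sigW
  list(statistic = W, p_value = 2 * pnorm(-abs(z)),
       method = "normal approximation")
}

#' Kolmogorov-Smirnov test of normality with estimated parameters
#'
#' Lilliefors-style: the KS statistic against a normal distribution with
#' the sample mean and SD, with the p-value obtained by Monte-Carlo
#' simulation under the null (parameters re-estimated in each draw).
#'
#' @param x Numeric sample, n >= 3.
#' @param n_mc Monte-Carlo draws for the p-value.
#' @param seed Integer seed.
#' @return List with `statistic`, `p_value`, `n_mc`.
#' @export
ks_normality <- function(x, n_mc = 2000L, seed = 1L) {
  n <- length(x)
  stopifnot(n >= 3L)
  D <- lilliefors_stat(x)
  set.seed(seed)
  Dnull <- replicate(n_mc, lilliefors_stat(rnorm(n)))
  list(statistic = D, p_value = (1 + sum(Dnull >= D)) / (n_mc + 1),
       n_mc = n_mc)
}

# sup |ECDF - Phi((x - mean)/sd)| evaluated at the sample points (both sides)
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  F <- pnorm(z)
  max(seq_len(n) / n - F, F - (seq_len(n) - 1) / n)
}

#' Power for the two-sample difference of proportions
#'
#' Normal-approximation (Rosner) power of the two-sided two-sample test of
#' proportions: both rejection tails are accumulated, so equal proportions
#' give power approximately `alpha`.
#'
#' @param p1,p2 True proportions in (0, 1).
#' @param n_per_group Subjects per group (equal groups).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_proportions <- function(p1, p2, n_per_group, alpha = 0.05) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, n_per_group >= 2)
  n <- n_per_group
  delta <- p1 - p2
  pbar <- (p1 + p2) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar) / n)
  se1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  z <- qnorm(1 - alpha / 2)
  pnorm((delta - z * se0) / se1) + pnorm((-delta - z * se0) / se1)
}

#' Group comparison of head-motion summaries
#'
#' Reduces each subject's six realignment-parameter traces to a scalar per
#' parameter -- either the summed scan-to-scan absolute difference or the
#' total within-session deviation (summed absolute deviation from the
#' session mean) -- and compares the groups with a pooled-variance t-test
#' per parameter.
#'
#' @param params_a,params_b Lists of `n_scans` x 6 matrices (one per
#'   subject).
#' @param measure `"scan_to_scan"` (default) or `"total_deviation"`.
#' @return Data frame with one row per parameter: `parameter`, `mean_a`,
#'   `mean_b`, `t`, `dof`, `p`.
#' @export
motion_summary_test <- function(params_a, params_b,
                                measure = c("scan_to_scan",
                                            "total_deviation")) {
  measure <- match.arg(measure)
  check <- function(lst) {
    stopifnot(length(lst) >= 2L)
    nc <- vapply(lst, ncol, integer(1L))
    nr <- vapply(lst, nrow, integer(1L))
    if (any(nc != 6L) || length(unique(nr)) != 1L)
      stop("each subject needs a matrix with 6 parameter columns of equal ",
           "length")
  }
  check(params_a); check(params_b)
  summarize <- function(m) {
    if (measure == "scan_to_scan") colSums(abs(diff(m)))
    else colSums(abs(sweep(m, 2L, colMeans(m))))
  }
  Sa <- t(vapply(params_a, summarize, numeric(6L)))
  Sb <- t(vapply(params_b, summarize, numeric(6L)))
  res <- lapply(1:6, function(j) {
    tt <- t.test(Sa[, j], Sb[, j], var.equal = TRUE)
    data.frame(parameter = colnames(params_a[[1L]])[j],
               mean_a = mean(Sa[, j]), mean_b = mean(Sb[, j]),
               t = unname(tt$statistic), dof = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, res)
}

#' @export
print.tmap <- function(x, ...) {
  ok <- !is.na(x$t)
  cat(sprintf("tmap: %d voxels (dof %d), max |t| = %.2f\n",
              sum(ok), x$dof, max(abs(x$t[ok]))))
  cat(sprintf("  FDR q = %g: %d significant voxel(s)\n", x$q, sum(x$flags)))
  invisible(x)
}
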