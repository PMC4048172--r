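#' Simulate block-design BOLD time series for a two-group cohort
#'
#' Per masked voxel the series is
#' `baseline + responsiveness * (boxcar convolved with HRF) + drift + AR(1) noise`,
#' with runs generated independently. Informative voxels' responsiveness
#' differs between groups by `effect_sizes * noise_sd` of the ground truth;
#' optional i.i.d. between-subject amplitude variability (`amp_sd`) makes the
#' downstream contrast maps noisy even with clean scanner noise.
#'
#' @param mask A [make_mask()] result.
#' @param truth A [ground_truth()]; its `effect_sizes * noise_sd` become the
#'   chronic-group responsiveness shift at the informative voxels (contrast
#'   units).
#' @param design A [block_design()].
#' @param n_per_group Subjects per group.
#' @param ar_coef AR(1) coefficient of the scanner noise, in (-1, 1).
#' @param noise_sd Innovation SD of the AR(1) noise (0 for noiseless).
#' @param drift_amp Amplitude of the slow scanner drift (0 disables).
#' @param amp_sd SD of i.i.d. between-subject responsiveness variability.
#' @param baseline Constant signal level.
#' @param seed Integer seed.
#' @return Object of class `bold_cohort`: `series` (list of voxels x scans
#'   matrices, runs concatenated), `labels`, `table`, `mask`, `truth`,
#'   `design`.
#' @export
simulate_bold_cohort <- function(mask, truth, design = block_design(),
                                 n_per_group = 13L, ar_coef = 0.3,
                                 noise_sd = 1, drift_amp = 0, amp_sd = 0,
                                 baseline = 100, seed = truth$seed) {
  stopifnot(inherits(mask, "mask_volume"), inherits(truth, "ground_truth"),
            inherits(design, "block_design"))
  if (abs(ar_coef) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  set.seed(seed)
  V <- mask$n_voxels
  n <- 2L * n_per_group
  ns <- design$n_scans_per_run
  reg <- hrf_convolve(build_boxcar(design), design$tr)
  reg_all <- rep(reg, design$n_runs)
  Tn <- ns * design$n_runs
  shift <- numeric(V)
  shift[truth$informative_indices] <- truth$effect_sizes * truth$noise_sd
  # slow drift basis: slowest two non-constant DCT components per run
  drift_basis <- dct_highpass_basis(ns, design$tr, cutoff_s = 3 * design$tr)
  drift_basis <- drift_basis[, 2:min(3L, ncol(drift_basis)), drop = FALSE]
  labels <- factor(rep(c("chronic", "normal"), each = n_per_group),
                   levels = c("normal", "chronic"))
  tab <- simulate_cohort_table(n_per_group, seed = seed + 1L)
  series <- vector("list", n)
  names(series) <- tab$id
  for (s in seq_len(n)) {
    amp <- (if (labels[s] == "chronic") shift else numeric(V)) +
      (if (amp_sd > 0) rnorm(V, 0, amp_sd) else 0)
    y <- matrix(baseline, V, Tn) + outer(amp, reg_all)
    for (r in seq_len(design$n_runs)) {
      cols <- (r - 1L) * ns + seq_len(ns)
      if (drift_amp > 0) {
        coefs <- matrix(rnorm(V * ncol(drift_basis), 0, drift_amp),
                        V, ncol(drift_basis))
        y[, cols] <- y[, cols] + coefs %*% t(drift_basis)
      }
      if (noise_sd > 0)
        y[, cols] <- y[, cols] + ar1_noise(V, ns, ar_coef, noise_sd)
    }
    series[[s]] <- y
  }
  structure(list(series = series, labels = labels, table = tab,
                 mask = mask, truth = truth, design = design,
                 seed = as.integer(seed)),
            class = "bold_cohort")
}

# V x n matrix of stationary AR(1) noise rows
ar1_noise <- function(V, n, phi, sd_innov) {
  e <- matrix(rnorm(V * n, 0, sd_innov), V, n)
  out <- e
  out[, 1L] <- e[, 1L] / sqrt(1 - phi^2)  # stationary start
  for (t in 2:n) out[, t] <- phi * out[, t - 1L] + e[, t]
  out
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf(
    "bold_cohort: %d subjects x %d voxels x %d scans (%d run(s) of %d, TR %g s)\n",
    length(x$series), x$mask$n_voxels,
    x$design$n_scans_per_run * x$design$n_runs, x$design$n_runs,
    x$design$n_scans_per_run, x$design$tr))
  invisible(x)
}
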