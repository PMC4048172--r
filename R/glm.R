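#' Block-design timing parameters
#'
#' Defaults mirror a 14 s stimulation / 14 s rest block design repeated five
#' times per run, two runs of 86 scans at TR 3.67 s.
#'
#' @param tr Repetition time in seconds.
#' @param n_scans_per_run Scans per run.
#' @param n_runs Number of runs.
#' @param block_s Duration of each stimulation (and each rest) block, s.
#' @param n_cycles Number of stimulation/rest cycles per run.
#' @param first_block Which condition starts the run (`"stim"` or `"rest"`).
#' @return Object of class `block_design`.
#' @export
block_design <- function(tr = 3.67, n_scans_per_run = 86L, n_runs = 2L,
                         block_s = 14, n_cycles = 5L, first_block = "stim") {
  stopifnot(tr > 0, n_scans_per_run >= 1, n_runs >= 1, block_s >= 0,
            n_cycles >= 1)
  first_block <- match.arg(first_block, c("stim", "rest"))
  if (n_cycles * 2 * block_s > n_scans_per_run * tr)
    stop("design does not fit in the run: n_cycles * 2 * block_s exceeds ",
         "run duration")
  structure(list(tr = tr, n_scans_per_run = as.integer(n_scans_per_run),
                 n_runs = as.integer(n_runs), block_s = block_s,
                 n_cycles = as.integer(n_cycles), first_block = first_block),
            class = "block_design")
}

#' Boxcar stimulus indicator sampled at scan times
#'
#' Value 1 while stimulation is on and 0 otherwise, evaluated at acquisition
#' times `t = (i - 1) * tr` for one run.
#'
#' @param design A [block_design()].
#' @return Numeric vector of length `n_scans_per_run`.
#' @export
build_boxcar <- function(design) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_scans_per_run
  if (design$block_s == 0) return(numeric(n))
  t <- (seq_len(n) - 1) * design$tr
  cycle <- t %% (2 * design$block_s)
  on <- if (design$first_block == "stim") cycle < design$block_s
        else cycle >= design$block_s
  as.numeric(on & t < design$n_cycles * 2 * design$block_s)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma shape: a response gamma density peaking at 5-6 s
#' minus an undershoot gamma peaking near 15 s scaled by `1/ratio`.
#'
#' @param t Time in seconds (>= 0).
#' @param peak_shape,undershoot_shape Gamma shape parameters of the response
#'   and undershoot components (rate 1).
#' @param ratio Response-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_canonical <- function(t, peak_shape = 6, undershoot_shape = 16,
                          ratio = 6) {
  dgamma(t, shape = peak_shape, rate = 1) -
    dgamma(t, shape = undershoot_shape, rate = 1) / ratio
}

#' Convolve a stimulus vector with the canonical HRF
#'
#' Discrete approximation of the continuous convolution: the HRF is sampled
#' at the scan interval over a 32 s support and the convolution sum is scaled
#' by `tr`, truncated to the input length.
#'
#' @param stimulus Per-scan stimulus vector (one run).
#' @param tr Sampling interval in seconds.
#' @return Vector of the same length as `stimulus`.
#' @export
hrf_convolve <- function(stimulus, tr) {
  stopifnot(tr > 0)
  n <- length(stimulus)
  h <- hrf_canonical(seq(0, 32, by = tr))
  out <- convolve(stimulus, rev(h), type = "open")[seq_len(n)] * tr
  as.numeric(out)
}

#' Discrete-cosine high-pass drift basis
#'
#' Orthonormal DCT-II basis covering fluctuations slower than the cutoff
#' period: `K = floor(2 * n_scans * tr / cutoff_s) + 1` columns including
#' the constant.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time, s.
#' @param cutoff_s High-pass cutoff period, s (default 128; `Inf` keeps only
#'   the constant).
#' @return `n_scans` x `K` matrix with orthonormal columns.
#' @export
dct_highpass_basis <- function(n_scans, tr, cutoff_s = 128) {
  stopifnot(n_scans >= 1, tr > 0, cutoff_s > 2 * tr)
  K <- if (is.finite(cutoff_s)) floor(2 * n_scans * tr / cutoff_s) + 1L
       else 1L
  t <- seq_len(n_scans) - 1L
  basis <- vapply(seq_len(K) - 1L, function(r)
    cos(pi * (2 * t + 1) * r / (2 * n_scans)), numeric(n_scans))
  basis <- matrix(basis, n_scans, K)
  sweep(basis, 2L, sqrt(colSums(basis^2)), "/")
}

#' Assemble the first-level design matrix
#'
#' One shared task regressor (boxcar convolved with the canonical HRF),
#' a per-run intercept, and per-run non-constant DCT drift columns, with
#' runs concatenated row-wise.
#'
#' @param design A [block_design()].
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return Matrix with attributes `task_col` (column index of the task
#'   regressor), `run` (run index per row), and `K` (DCT columns per run,
#'   constant included).
#' @export
build_design_matrix <- function(design, cutoff_s = 128) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_scans_per_run
  reg <- hrf_convolve(build_boxcar(design), design$tr)
  dct <- dct_highpass_basis(n, design$tr, cutoff_s)
  K <- ncol(dct)
  drift <- dct[, -1L, drop = FALSE]  # constant carried by the intercepts
  nr <- design$n_runs
  task <- rep(reg, nr)
  blocks <- lapply(seq_len(nr), function(r) {
    m <- matrix(0, n * nr, 1L + ncol(drift))
    rows <- (r - 1L) * n + seq_len(n)
    m[rows, 1L] <- 1
    if (ncol(drift)) m[rows, -1L] <- drift
    colnames(m) <- c(sprintf("run%d_mean", r),
                     if (ncol(drift)) sprintf("run%d_dct%d", r,
                                              seq_len(ncol(drift))))
    m
  })
  X <- cbind(task = task, do.call(cbind, blocks))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "task_col") <- 1L
  attr(X, "run") <- rep(seq_len(nr), each = n)
  attr(X, "K") <- K
  X
}

#' Fit the first-level GLM with AR(1) prewhitening
#'
#' Two-pass fit: ordinary least squares, a single lag-1 autocorrelation
#' estimate pooled over voxels from the residuals (within runs), then both
#' data and design are whitened by the AR(1) inverse square root and refit.
#' The contrast is the task-regressor coefficient (stimulation versus rest,
#' rest being baseline).
#'
#' @param series Numeric matrix, scans x voxels (a single voxel may be passed
#'   as a vector).
#' @param design_matrix A [build_design_matrix()] result (or any full-rank
#'   matrix with `task_col` and `run` attributes).
#' @return Object of class `glm_result`: `contrast` (per voxel), `beta`
#'   (coefficients x voxels), `sigma2`, `ar1` (pooled), `dof`.
#' @export
fit_glm_ar1 <- function(series, design_matrix) {
  Y <- as.matrix(series)
  X <- design_matrix
  if (nrow(Y) != nrow(X)) stop("series length does not match the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  run <- attr(X, "run") %||% rep(1L, nrow(X))
  task <- attr(X, "task_col") %||% 1L

  res <- qr.resid(qx, Y)
  # residuals at rounding-error scale (noiseless data): autocorrelation of
  # numerical noise is meaningless, define phi = 0
  phi <- if (sum(res^2) <= 1e-12 * sum(Y^2)) 0 else pooled_ar1(res, run)
  # OLS residuals attenuate the autocorrelation (the drift columns absorb
  # low-frequency variance); invert the expected attenuation curve of this
  # design to de-bias the pooled estimate
  if (phi != 0) phi <- debias_ar1(phi, qx, run)
  Xw <- ar1_whiten(X, phi, run)
  Yw <- ar1_whiten(Y, phi, run)
  qw <- qr(Xw)
  beta <- qr.coef(qw, Yw)
  resw <- qr.resid(qw, Yw)
  dof <- nrow(X) - qx$rank
  sigma2 <- colSums(resw^2) / dof
  structure(list(contrast = as.numeric(beta[task, ]),
                 beta = beta, sigma2 = as.numeric(sigma2),
                 ar1 = phi, dof = dof),
            class = "glm_result")
}

# lag-1 autocorrelation of residuals pooled over voxels, within runs
pooled_ar1 <- function(res, run) {
  num <- 0; den <- 0
  for (r in unique(run)) {
    rr <- res[run == r, , drop = FALSE]
    n <- nrow(rr)
    if (n < 2L) next
    num <- num + sum(rr[-1L, ] * rr[-n, ])
    den <- den + sum(rr^2)
  }
  if (den <= 0) return(0)
  phi <- num / den
  max(min(phi, 0.99), -0.99)
}

# Map a raw residual lag-1 ratio to the AR(1) coefficient whose OLS
# residuals would show that ratio in expectation. With M the residual maker
# and P the symmetrized within-run lag-1 pairing matrix,
#   E[num] = tr(M P M Sigma),  E[den] = tr(M Sigma),
# and Sigma_ij = phi^|i-j| (the 1/(1-phi^2) scale cancels). Both traces are
# polynomials in phi through the within-run lag sums of M P M and M, so the
# expectation curve is cheap to evaluate and invert.
debias_ar1 <- function(rho_raw, qx, run) {
  n <- nrow(qx$qr)
  Q <- qr.Q(qx)
  M <- diag(n) - tcrossprod(Q)
  same_run <- outer(run, run, "==")
  P <- matrix(0, n, n)
  idx <- which(abs(row(P) - col(P)) == 1L & same_run)
  P[idx] <- 0.5
  A <- M %*% P %*% M
  lag <- abs(row(P) - col(P))
  lagsum <- function(C) {
    agg <- rowsum(C[same_run], lag[same_run])
    v <- numeric(n)
    v[as.integer(rownames(agg)) + 1L] <- agg
    v
  }
  cn <- lagsum(A)
  cd <- lagsum(M)
  expected_ratio <- function(phi) {
    pw <- phi^(0:(n - 1L))
    sum(cn * pw) / sum(cd * pw)
  }
  lo <- -0.95; hi <- 0.95
  glo <- expected_ratio(lo); ghi <- expected_ratio(hi)
  if (rho_raw <= min(glo, ghi)) return(if (glo < ghi) lo else hi)
  if (rho_raw >= max(glo, ghi)) return(if (glo < ghi) hi else lo)
  stats::uniroot(function(phi) expected_ratio(phi) - rho_raw,
                 c(lo, hi), tol = 1e-10)$root
}

# AR(1) inverse-square-root transform applied within each run:
# x*_1 = sqrt(1 - phi^2) x_1, x*_t = x_t - phi x_{t-1}
ar1_whiten <- function(x, phi, run) {
  x <- as.matrix(x)
  out <- x
  for (r in unique(run)) {
    rows <- which(run == r)
    n <- length(rows)
    xr <- x[rows, , drop = FALSE]
    wr <- xr
    wr[1L, ] <- sqrt(1 - phi^2) * xr[1L, ]
    if (n > 1L) wr[-1L, ] <- xr[-1L, , drop = FALSE] -
        phi * xr[-n, , drop = FALSE]
    out[rows, ] <- wr
  }
  out
}

#' First-level contrasts for a simulated BOLD cohort
#'
#' Runs [fit_glm_ar1()] per subject and assembles the resulting contrast
#' maps into a `contrast_cohort` usable by the decoder.
#'
#' @param bold A [simulate_bold_cohort()] result.
#' @param cutoff_s High-pass cutoff period, s.
#' @return A `contrast_cohort` (maps, labels, mask, truth) plus per-subject
#'   `fit_info` (ar1, dof, K).
#' @export
glm_contrast_cohort <- function(bold, cutoff_s = 128) {
  stopifnot(inherits(bold, "bold_cohort"))
  X <- build_design_matrix(bold$design, cutoff_s)
  fits <- lapply(bold$series, function(y) fit_glm_ar1(t(y), X))
  maps <- do.call(rbind, lapply(fits, function(f) f$contrast))
  rownames(maps) <- names(bold$series)
  info <- data.frame(id = names(bold$series),
                     ar1 = vapply(fits, function(f) f$ar1, numeric(1L)),
                     dof = vapply(fits, function(f) f$dof, numeric(1L)),
                     K = attr(X, "K"))
  structure(list(maps = maps, labels = bold$labels, table = bold$table,
                 mask = bold$mask, truth = bold$truth, fit_info = info),
            class = "contrast_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
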