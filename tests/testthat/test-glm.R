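test_that("boxcar matches brute-force enumeration of scan times", {
  d <- block_design()
  b <- build_boxcar(d)
  expect_length(b, 86L)
  # independent enumeration over all scan times
  t <- (0:85) * d$tr
  expected <- as.numeric(t %% 28 < 14 & t < 140)
  expect_equal(b, expected)
  # exactly 5 on-epochs, and total on-time 5 x 14 s
  expect_equal(sum(diff(c(0, b)) == 1), 5L)
  expect_equal(d$n_cycles * d$block_s, 70)
  # degenerate: zero-length blocks give an all-zero regressor
  d0 <- block_design(block_s = 0)
  expect_equal(build_boxcar(d0), numeric(86))
})

test_that("block designs that do not fit in a run are rejected", {
  expect_error(block_design(n_cycles = 20), "does not fit")
  expect_error(simulate_bold_cohort(tiny_mask(),
                                    ground_truth(seed = 1),
                                    ar_coef = 1.2),
               "AR\\(1\\)")
})

test_that("HRF convolution is linear and peaks where the kernel peaks", {
  tr <- 3.67
  stim <- c(1, rep(0, 85))  # unit impulse at scan 0
  out <- hrf_convolve(stim, tr)
  expect_equal(hrf_convolve(numeric(86), tr), numeric(86))
  expect_equal(hrf_convolve(3.7 * stim, tr), 3.7 * out, tolerance = 1e-12)
  # fine-grid numerical convolution oracle: response peak near 5 s
  tt <- seq(0, 32, by = 0.01)
  fine <- hrf_canonical(tt)
  peak_s <- tt[which.max(fine)]
  expect_equal(peak_s, 5, tolerance = 0.05)
  expect_equal((which.max(out) - 1) * tr,
               round(peak_s / tr) * tr, tolerance = 1e-9)
  # impulse response equals the sampled kernel (scaled by tr) within the
  # 32 s kernel support, and is negligible beyond it
  support <- seq_along(seq(0, 32, by = tr))
  expect_lt(max(abs(out[support] -
                      hrf_canonical((support - 1) * tr) * tr)), 1e-10)
  expect_lt(max(abs(out[-support])), 1e-12)
})

test_that("DCT basis has the prescribed size and is orthonormal", {
  B <- dct_highpass_basis(86, 3.67, 128)
  expect_equal(ncol(B), floor(2 * 86 * 3.67 / 128) + 1)  # 5 columns
  expect_equal(crossprod(B), diag(5), tolerance = 1e-12)
  expect_equal(ncol(dct_highpass_basis(86, 3.67, Inf)), 1L)
  expect_error(dct_highpass_basis(86, 3.67, 5), "cutoff")
})

test_that("DCT projection removes slow drift but little white noise", {
  n <- 86; tr <- 3.67
  B <- dct_highpass_basis(n, tr, 128)
  t <- (0:(n - 1)) * tr
  slow <- cos(2 * pi * t / 256)          # period 256 s, below cutoff
  resid <- slow - B %*% crossprod(B, slow)
  expect_lt(sum(resid^2) / sum((slow - mean(slow))^2), 0.10)
  set.seed(1)
  kept <- replicate(300, {
    e <- rnorm(n)
    r <- e - B %*% crossprod(B, e)
    sum(r^2) / sum(e^2)
  })
  expect_gt(mean(kept), 1 - ncol(B) / n - 0.05)
})

test_that("noiseless task data is recovered exactly with zero ar1", {
  X <- build_design_matrix(block_design())
  y <- 2 * X[, 1]
  f <- fit_glm_ar1(y, X)
  expect_equal(f$contrast, 2, tolerance = 1e-8)
  expect_equal(f$ar1, 0)
  expect_equal(f$dof, nrow(X) - ncol(X))
})

test_that("rank-deficient designs are reported with the offending column", {
  X <- build_design_matrix(block_design())
  Xbad <- cbind(X, dup = X[, 2])
  attr(Xbad, "task_col") <- 1L
  attr(Xbad, "run") <- attr(X, "run")
  expect_error(fit_glm_ar1(rnorm(nrow(X)), Xbad), "dup")
})

test_that("pooled AR(1) estimate recovers the generating coefficient", {
  X <- build_design_matrix(block_design())
  set.seed(21)
  # white noise: estimates concentrate near zero
  phi0 <- replicate(60, {
    fit_glm_ar1(matrix(rnorm(172 * 10), 172, 10), X)$ar1
  })
  expect_gte(mean(abs(phi0) < 0.15), 0.95)
  # AR(1) with phi = 0.3: de-biased pooled estimate within +/- 0.1
  phi3 <- replicate(60, {
    y <- t(painmvpa:::ar1_noise(10, 172, 0.3, 1))
    fit_glm_ar1(y, X)$ar1
  })
  expect_gte(mean(abs(phi3 - 0.3) < 0.1), 0.95)
  expect_lt(abs(mean(phi3) - 0.3), 0.03)
})

test_that("whitening leaves residuals with little lag-1 autocorrelation", {
  X <- build_design_matrix(block_design())
  run <- attr(X, "run")
  set.seed(31)
  lag1 <- replicate(40, {
    y <- t(painmvpa:::ar1_noise(10, 172, 0.4, 1))
    f <- fit_glm_ar1(y, X)
    yw <- painmvpa:::ar1_whiten(y, f$ar1, run)
    xw <- painmvpa:::ar1_whiten(X, f$ar1, run)
    qw <- qr(xw)
    raw <- painmvpa:::pooled_ar1(qr.resid(qw, yw), run)
    # residual autocorrelation on the same de-biased scale as the estimate
    painmvpa:::debias_ar1(raw, qw, run)
  })
  expect_lt(abs(mean(lag1)), 0.05)
})

test_that("contrast is invariant to drift spanned by the basis", {
  X <- build_design_matrix(block_design())
  run <- attr(X, "run")
  set.seed(41)
  y <- rnorm(172)
  f0 <- fit_glm_ar1(y, X)
  drift_cols <- X[, -1, drop = FALSE]
  y2 <- y + drift_cols %*% runif(ncol(drift_cols), -5, 5)
  f2 <- fit_glm_ar1(as.numeric(y2), X)
  expect_equal(f0$contrast, f2$contrast, tolerance = 1e-8)
})

test_that("zero-noise BOLD cohorts reproduce programmed responsiveness", {
  m <- tiny_mask()
  idx <- c(2L, 9L); eff <- c(1.5, -0.8)
  tr <- ground_truth(idx, eff, seed = 2)
  bo <- simulate_bold_cohort(m, tr, block_design(), n_per_group = 2,
                             ar_coef = 0.3, noise_sd = 0, drift_amp = 0,
                             amp_sd = 0, seed = 2)
  cc <- glm_contrast_cohort(bo)
  programmed <- numeric(m$n_voxels); programmed[idx] <- eff
  for (s in which(cc$labels == "chronic"))
    expect_equal(unname(cc$maps[s, ]), programmed, tolerance = 1e-8)
  for (s in which(cc$labels == "normal"))
    expect_equal(unname(cc$maps[s, ]), numeric(m$n_voxels),
                 tolerance = 1e-8)
  # zero responsiveness, noise, and drift: constant series at baseline
  bo0 <- simulate_bold_cohort(m, ground_truth(seed = 3), block_design(),
                              n_per_group = 2, noise_sd = 0, drift_amp = 0,
                              amp_sd = 0, baseline = 100, seed = 3)
  expect_true(all(bo0$series[[1]] == 100))
})
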