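test_that("two-sample t-maps match hand-computed pooled t", {
  # A = {1,2,3}, B = {4,5,6}: t = -3.674 with 4 dof
  A <- matrix(c(1, 2, 3), 3, 1); B <- matrix(c(4, 5, 6), 3, 1)
  tm <- two_sample_tmap(A, B)
  expect_equal(tm$t, (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3)))  # -3.674
  expect_equal(tm$t, -3.674, tolerance = 1e-4)
  expect_equal(tm$dof, 4L)
  # cross-check p against stats::t.test
  tt <- t.test(A, B, var.equal = TRUE)
  expect_equal(tm$p, tt$p.value, tolerance = 1e-12)
  # identical groups: all t exactly zero
  X <- matrix(rnorm(40), 4, 10)
  tm0 <- two_sample_tmap(X, X)
  expect_true(all(tm0$t == 0))
  # group-label swap negates every t
  Y <- matrix(rnorm(40), 4, 10)
  expect_equal(two_sample_tmap(X, Y)$t, -two_sample_tmap(Y, X)$t)
  # zero-variance voxel masked with a warning
  Xc <- X; Yc <- Y; Xc[, 3] <- 1; Yc[, 3] <- 1
  expect_warning(tmc <- two_sample_tmap(Xc, Yc), "zero pooled variance")
  expect_true(is.na(tmc$t[3]))
})

test_that("BH step-up flags match direct enumeration", {
  p <- c(0.001, 0.011, 0.021, 0.8)
  fdr <- fdr_threshold(p, q = 0.05)
  expect_equal(fdr$flags, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr$threshold, 0.021)
  # direct step-up oracle on random p-values
  set.seed(4)
  for (rep in 1:20) {
    pv <- runif(50)^2
    m <- length(pv)
    ord <- order(pv)
    below <- which(pv[ord] <= seq_len(m) * 0.05 / m)
    flags_oracle <- rep(FALSE, m)
    if (length(below)) flags_oracle[ord[seq_len(max(below))]] <- TRUE
    expect_equal(fdr_threshold(pv, 0.05)$flags, flags_oracle)
  }
  # invariance to input order
  pv <- runif(30)
  perm <- sample(30)
  expect_equal(fdr_threshold(pv, 0.1)$flags[perm],
               fdr_threshold(pv[perm], 0.1)$flags)
  expect_error(fdr_threshold(numeric(0)), "empty")
  # all p = 1: nothing flagged
  expect_false(any(fdr_threshold(rep(1, 10))$flags))
  # flags are monotone in q
  pv <- runif(200)^1.5
  f01 <- fdr_threshold(pv, 0.01)$flags
  f10 <- fdr_threshold(pv, 0.10)$flags
  expect_true(all(f10[f01]))
})

test_that("BH keeps the false-flag proportion at or below q on nulls", {
  set.seed(14)
  frac <- replicate(300, {
    pv <- runif(1000)
    mean(fdr_threshold(pv, 0.05)$flags)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("threshold weighting reduces to scaling before the t-test", {
  set.seed(6)
  maps <- matrix(rnorm(26 * 15, mean = 0.3), 26, 15)
  groups <- factor(rep(c("chronic", "normal"), each = 13),
                   levels = c("chronic", "normal"))
  # unit weights reproduce the unweighted map exactly
  tm1 <- weighted_contrast_tmap(maps, rep(1, 26), groups)
  tm0 <- two_sample_tmap(maps[1:13, ], maps[14:26, ])
  expect_identical(tm1$t, tm0$t)
  # doubling one group's weights equals recomputing by hand
  w <- c(rep(2, 13), rep(1, 13))
  tmw <- weighted_contrast_tmap(maps, w, groups)
  oracle <- two_sample_tmap(2 * maps[1:13, ], maps[14:26, ])
  expect_equal(tmw$t, oracle$t)
  expect_false(isTRUE(all.equal(tmw$t, tm0$t)))
  expect_error(weighted_contrast_tmap(maps, w[-1], groups), "weight")
})

test_that("duration correlation maps behave at the extremes", {
  set.seed(7)
  dur <- c(0.5, 1, 2, 3, 5, 5, 4, 2, 1, 0.5, 3, 2, 1)
  maps <- matrix(rnorm(13 * 10), 13, 10)
  maps[, 4] <- 2 * dur              # exact linear relation
  tm <- duration_correlation_map(maps, dur)
  expect_equal(tm$r[4], 1, tolerance = 1e-12)
  expect_true(is.finite(tm$t[4]) && tm$t[4] > 1e10)
  expect_true(all(abs(tm$r[-4]) < 0.9))
  expect_error(duration_correlation_map(maps, rep(2, 13)), "constant")
  # planted slope is the top |r| voxel in most repeats
  hits <- vapply(1:40, function(k) {
    mm <- matrix(rnorm(13 * 30), 13, 30)
    mm[, 17] <- mm[, 17] + 0.8 * scale(dur)[, 1] * 2
    which.max(abs(duration_correlation_map(mm, dur)$r)) == 17
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("small-volume correction equals brute-force sphere restriction", {
  m <- small_test_mask()
  co <- null_cohort(seed = 21, mask = m)
  tm <- two_sample_tmap(co$maps[co$labels == "chronic", ],
                        co$maps[co$labels == "normal", ], mask = m)
  center <- m$coords_mm[50, ]
  svc <- small_volume_correction(tm, center, radius = 6, q = 0.05)
  d2 <- colSums((t(m$coords_mm) - center)^2)
  expect_setequal(svc$voxels, which(d2 <= 36))
  # radius covering one voxel reduces to that single test
  svc1 <- small_volume_correction(tm, center, radius = 0.5)
  expect_equal(svc1$voxels, 50L)
  expect_equal(svc1$flags, tm$p[50] <= 0.05)
  expect_error(small_volume_correction(tm, c(500, 500, 500), 8), "intersect")
})

test_that("wilcoxon exact path reproduces full enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 2 / 20)  # C(6,3) = 20 assignments, 2 as extreme
  # identical samples: p near 1
  wi <- wilcoxon_rank_sum(c(1, 2, 7), c(1, 2, 7))
  expect_gte(wi$p_value, 0.9)
  # cross-check the exact path against stats::wilcox.test (no ties)
  set.seed(9)
  a <- rnorm(6); b <- rnorm(6) + 0.5
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  # exact and normal-approximation paths agree at combined n = 12
  pe <- wilcoxon_rank_sum(a, b, exact_max = 12)$p_value
  pn <- wilcoxon_rank_sum(a, b, exact_max = 0)$p_value
  expect_lt(abs(pe - pn), 0.02)
})

test_that("KS normality statistic equals the direct ECDF supremum", {
  set.seed(10)
  x <- rnorm(26)
  D <- ks_normality(x, n_mc = 200, seed = 1)$statistic
  # brute force over sample points, both one-sided gaps
  z <- (x - mean(x)) / sd(x)
  Fz <- pnorm(sort(z))
  n <- length(z)
  D_oracle <- max(pmax(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n))
  expect_equal(D, D_oracle, tolerance = 1e-12)
  # cross-check against the Lilliefors implementation in nortest
  skip_if_not_installed("nortest")
  expect_equal(D, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-10)
})

test_that("KS test rejects bimodal data and accepts normal data", {
  set.seed(12)
  rej <- vapply(1:40, function(k) {
    x <- c(rnorm(13, -2, 0.1), rnorm(13, 2, 0.1))
    ks_normality(x, n_mc = 200, seed = k)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  x <- rnorm(500)
  ks <- ks_normality(x, n_mc = 200, seed = 3)
  expect_lt(ks$statistic, 0.08)
  expect_gt(ks$p_value, 0.05)
})

test_that("two-proportion power matches its boundary cases and a simulation", {
  # equal proportions: power collapses to the test size
  expect_equal(power_two_proportions(0.4, 0.4, 50), 0.05, tolerance = 0.005)
  # monotone in effect size and in n
  eff <- vapply(c(0.5, 0.6, 0.7, 0.8), function(p1)
    power_two_proportions(p1, 0.4, 40), numeric(1))
  expect_true(all(diff(eff) > 0))
  nn <- vapply(c(10, 20, 40, 80), function(n)
    power_two_proportions(0.6, 0.4, n), numeric(1))
  expect_true(all(diff(nn) > 0))
  # simulation oracle for the mid case
  set.seed(13)
  n <- 50; B <- 40000
  x1 <- rbinom(B, n, 0.6); x2 <- rbinom(B, n, 0.4)
  ph1 <- x1 / n; ph2 <- x2 / n; pb <- (x1 + x2) / (2 * n)
  se0 <- sqrt(pb * (1 - pb) * 2 / n)
  z <- (ph1 - ph2) / se0
  sim_power <- mean(abs(z) > qnorm(0.975), na.rm = TRUE)
  # the normal-approximation power formula carries ~2-3 points of error
  # against the exact (binomial) rejection rate at n = 50
  expect_equal(power_two_proportions(0.6, 0.4, 50), sim_power,
               tolerance = 0.05)
})

test_that("motion summaries separate scaled groups and not identical ones", {
  mp <- simulate_motion_params(16, n_scans = 60, seed = 31)
  res0 <- motion_summary_test(mp[1:3], mp[1:3])
  expect_true(all(res0$t == 0))
  scaled <- lapply(mp[9:16], function(m) m * 3)
  res1 <- motion_summary_test(scaled, mp[1:8])
  expect_true(all(res1$p < 0.05))
  expect_equal(nrow(res1), 6L)
  # total-deviation variant (noisier summary, needs the larger groups)
  res2 <- motion_summary_test(scaled, mp[1:8], measure = "total_deviation")
  expect_true(all(res2$p < 0.05))
  # null simulated traces: mostly non-significant per parameter
  set.seed(33)
  ps <- replicate(20, {
    mm <- simulate_motion_params(12, n_scans = 60,
                                 seed = sample.int(1e6, 1))
    min(motion_summary_test(mm[1:6], mm[7:12])$p)
  })
  expect_gte(mean(ps > 0.05 / 6), 0.7)  # Bonferroni-level exceedances rare
  expect_error(motion_summary_test(mp[1:2],
                                   list(mp[[3]][, 1:5], mp[[4]][, 1:5])),
               "6 param")
})
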