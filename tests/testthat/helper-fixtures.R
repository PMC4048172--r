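# Shared small fixtures, built once per test run.

# single small sphere, ~19 voxels: cheapest valid mask
tiny_mask <- function() {
  make_mask(c(16L, 16L, 16L),
            list(list(label = "A", center = c(0, 0, 0), radius = 3)),
            affine = mni_affine(2, c(-16, -16, -16)))
}

# two disjoint spheres with distinct labels
two_sphere_mask <- function(r1 = 4, r2 = 6) {
  make_mask(c(24L, 24L, 24L),
            list(list(label = "L", center = c(-10, 0, 0), radius = r1),
                 list(label = "R", center = c(10, 0, 0), radius = r2)),
            affine = mni_affine(2, c(-24, -24, -24)))
}

# standard strong-effect cohort on the 243-voxel three-sphere mask
strong_cohort <- function(seed = 42L, n_per_group = 13L) {
  m <- small_test_mask()
  tr <- ground_truth(c(5L, 100L, 200L), c(-2, -2, 2), seed = seed)
  simulate_contrast_cohort(m, tr, n_per_group)
}

null_cohort <- function(seed = 1L, mask = small_test_mask()) {
  simulate_contrast_cohort(mask, ground_truth(integer(0), 0, seed = seed),
                           13L)
}

# brute-force voxel count of a sphere on a grid (independent of make_mask)
count_sphere_voxels <- function(shape, affine, center, radius) {
  g <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                             k = 0:(shape[3] - 1)))
  mm <- t(affine %*% rbind(t(g), 1))[, 1:3]
  sum((mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
        (mm[, 3] - center[3])^2 <= radius^2)
}

# brute-force maximizer of the penalized logistic log-likelihood at fixed
# prior precisions: cyclic grid refinement over each coordinate
grid_map_oracle <- function(X, y, alpha, bias_prec = 1e-10,
                            span = 8, sweeps = 60) {
  obj <- function(w, b) {
    eta <- X %*% w + b
    mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu)) - 0.5 * sum(alpha * w^2)
  }
  w <- numeric(ncol(X)); b <- 0
  width <- span
  for (s in seq_len(sweeps)) {
    for (j in seq_len(ncol(X))) {
      grid <- w[j] + seq(-width, width, length.out = 21)
      vals <- vapply(grid, function(g) {
        wj <- w; wj[j] <- g; obj(wj, b)
      }, numeric(1))
      w[j] <- grid[which.max(vals)]
    }
    grid <- b + seq(-width, width, length.out = 21)
    vals <- vapply(grid, function(g) obj(w, g), numeric(1))
    b <- grid[which.max(vals)]
    width <- width * 0.7
  }
  list(w = w, bias = b)
}
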