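#' Voxel-to-MNI affine for an isotropic grid
#'
#' @param voxel_mm Voxel edge length in mm (default 2).
#' @param origin_mm MNI-mm coordinate of voxel (0, 0, 0). The default places
#'   a 91 x 109 x 91 grid over the standard MNI bounding box
#'   x -90..90, y -126..90, z -72..108.
#' @return 4 x 4 affine matrix mapping 0-based voxel indices to mm.
#' @export
mni_affine <- function(voxel_mm = 2, origin_mm = c(-90, -126, -72)) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- origin_mm
  aff
}

#' Build an analysis mask from labeled spherical regions
#'
#' Stands in for an anatomical-atlas mask of pain-processing regions: the
#' union of spheres (in mm) over a regular voxel grid. Voxels inside more
#' than one sphere take the label of the first-listed region.
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param region_specs List of regions, each a list with `label` (character),
#'   `center` (MNI mm, length 3) and `radius` (mm, >= 0).
#' @param affine 4 x 4 voxel-index (0-based) to mm map; default [mni_affine()].
#' @return An object of class `mask_volume`: logical `grid`, the `affine`,
#'   `n_voxels`, and per-voxel `labels`, 0-based `voxel_index` (n x 3) and
#'   `coords_mm` (n x 3). Voxel order is column-major grid order.
#' @export
make_mask <- function(shape, region_specs, affine = mni_affine()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            is.list(region_specs), length(region_specs) >= 1L,
            all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  grid_lab <- array(0L, dim = shape)
  for (r in seq_along(region_specs)) {
    spec <- region_specs[[r]]
    stopifnot(!is.null(spec$label), length(spec$center) == 3L,
              spec$radius >= 0)
    sel <- sphere_voxels(shape, affine, spec$center, spec$radius)
    if (nrow(sel) == 0L)
      stop("region '", spec$label, "' covers no voxel inside the grid")
    idx <- sel[, 1L] + shape[1L] * (sel[, 2L] + shape[2L] * sel[, 3L]) + 1L
    fresh <- grid_lab[idx] == 0L   # first-listed region wins overlaps
    grid_lab[idx[fresh]] <- r
  }
  inside <- which(grid_lab > 0L)
  if (length(inside) == 0L) stop("mask is empty")
  grid <- array(FALSE, dim = shape)
  grid[inside] <- TRUE
  vi <- arrayInd(inside, shape) - 1L
  mm <- t(affine %*% rbind(t(vi), 1))[, 1:3, drop = FALSE]
  labels <- vapply(region_specs, function(s) s$label, character(1L))
  structure(list(grid = grid, affine = affine,
                 n_voxels = length(inside),
                 labels = labels[grid_lab[inside]],
                 voxel_index = vi, coords_mm = mm, shape = shape),
            class = "mask_volume")
}

# 0-based voxel indices whose centers lie within `radius` mm of `center`
sphere_voxels <- function(shape, affine, center, radius) {
  inv <- solve(affine)
  cv <- (inv %*% c(center, 1))[1:3]
  vox_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  lo <- pmax(floor(cv - radius / vox_mm - 1), 0)
  hi <- pmin(ceiling(cv + radius / vox_mm + 1), shape - 1)
  if (any(lo > hi)) return(matrix(integer(0), 0L, 3L))
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- t(affine %*% rbind(t(g), 1))[, 1:3, drop = FALSE]
  d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
        (mm[, 3] - center[3])^2
  g[d2 <= radius^2, , drop = FALSE]
}

#' Default five-region pain mask
#'
#' Left-lateralized spheres standing in for the pain-processing regions used
#' for decoder feature selection: primary and secondary somatosensory cortex,
#' inferior parietal cortex, insula, and anterior cingulate cortex. Radii are
#' sized so the mask holds approximately 6686 voxels at 2 mm resolution.
#'
#' @param shape Grid dimensions (default full MNI 2 mm box).
#' @param affine Voxel-to-mm map.
#' @return A `mask_volume`.
#' @export
default_pain_mask <- function(shape = c(91L, 109L, 91L), affine = mni_affine()) {
  make_mask(shape, pain_region_specs(), affine = affine)
}

# canonical region centers (MNI mm) and radii for the default mask
pain_region_specs <- function() {
  list(list(label = "S1",     center = c(-40, -26, 54), radius = 13.6),
       list(label = "S2",     center = c(-52, -22, 16), radius = 13.6),
       list(label = "IPC",    center = c(-54, -48, 30), radius = 13.6),
       list(label = "insula", center = c(-38,   2,  2), radius = 13.6),
       list(label = "ACC",    center = c( 0,   18, 34), radius = 13.6))
}

#' Compact low-dimensional mask for simulation studies
#'
#' A small three-sphere mask (a few hundred voxels) used where the property
#' under study does not depend on the mask dimensionality, e.g. null-cohort
#' type-I-error Monte Carlo.
#'
#' @param radius Sphere radius in mm.
#' @return A `mask_volume`.
#' @export
small_test_mask <- function(radius = 5) {
  make_mask(c(32L, 32L, 32L),
            list(list(label = "A", center = c(-20, -20, -20), radius = radius),
                 list(label = "B", center = c(0, 0, 0),       radius = radius),
                 list(label = "C", center = c(20, 20, 20),    radius = radius)),
            affine = mni_affine(2, c(-32, -32, -32)))
}

#' Scattered-voxel mask with effectively independent features
#'
#' Single-voxel regions placed on a lattice with spacing well beyond the
#' default 8 mm smoothing kernel, so the masked noise features are
#' essentially uncorrelated. Used for null-cohort Monte Carlo where the
#' behavior under study is dimension-free and near-duplicate voxels would
#' only slow the decoder down.
#'
#' @param spacing_mm Lattice spacing in mm.
#' @return A `mask_volume` of 18 voxels.
#' @export
scatter_mask <- function(spacing_mm = 24) {
  centers <- as.matrix(expand.grid(x = c(-1, 0, 1) * spacing_mm,
                                   y = c(-1, 0, 1) * spacing_mm,
                                   z = c(-0.5, 0.5) * spacing_mm))
  specs <- lapply(seq_len(nrow(centers)), function(i)
    list(label = sprintf("v%02d", i), center = centers[i, ], radius = 0))
  extent <- 2L * ceiling((spacing_mm + 8) / 2)  # voxels; also mm half-width
  make_mask(rep(extent, 3L), specs,
            affine = mni_affine(2, rep(-extent, 3L)))
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume: %d voxels on a %s grid\n", x$n_voxels,
              paste(x$shape, collapse = " x ")))
  print(table(x$labels))
  invisible(x)
}
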