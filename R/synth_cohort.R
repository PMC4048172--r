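#' Ground-truth specification for a synthetic cohort
#'
#' Defines which mask voxels carry a group effect and how large it is.
#' Effect sizes are signed standardized mean differences (Cohen's d units)
#' of chronic minus normal: negative values emulate voxels where the chronic
#' group responds less (as in somatosensory cortex), positive values voxels
#' where it responds more (as in inferior parietal cortex).
#'
#' @param informative_indices 1-based mask-voxel indices carrying an effect.
#' @param effect_sizes Signed effects in units of the noise SD, recycled to
#'   the length of `informative_indices`.
#' @param noise_sd Marginal SD of the smoothed contrast noise.
#' @param smooth_fwhm Spatial smoothness (FWHM, mm) of the noise field.
#' @param seed Integer seed used by the generators when none is passed.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(informative_indices = integer(0), effect_sizes = 0,
                         noise_sd = 1, smooth_fwhm = 8, seed = 1L) {
  informative_indices <- as.integer(informative_indices)
  stopifnot(all(informative_indices >= 1L), !anyDuplicated(informative_indices),
            all(is.finite(effect_sizes)), noise_sd > 0, smooth_fwhm >= 0)
  effect_sizes <- rep_len(as.numeric(effect_sizes),
                          length(informative_indices))
  structure(list(informative_indices = informative_indices,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 smooth_fwhm = smooth_fwhm, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate a two-group cohort of masked contrast maps
#'
#' Each subject's contrast map is spatially smoothed Gaussian noise over the
#' mask; chronic-group subjects additionally receive
#' `effect_sizes * noise_sd` at the informative voxels. The noise field is
#' generated on the mask bounding box (plus kernel support), smoothed, and
#' rescaled so its marginal SD equals `noise_sd` exactly at every voxel, so
#' effect sizes are interpretable as Cohen's d.
#'
#' @param mask A [make_mask()] result.
#' @param truth A [ground_truth()].
#' @param n_per_group Subjects per group (>= 2; default 13).
#' @param seed Seed; defaults to `truth$seed`.
#' @return Object of class `contrast_cohort`: `maps` (subjects x voxels
#'   matrix, chronic rows first), `labels` (factor, levels normal/chronic),
#'   `table` (demographics, see [simulate_cohort_table()]), `mask`, `truth`.
#' @export
simulate_contrast_cohort <- function(mask, truth, n_per_group = 13L,
                                     seed = truth$seed) {
  stopifnot(inherits(mask, "mask_volume"), inherits(truth, "ground_truth"))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L)
    stop("n_per_group must be >= 2 (leave-one-out is degenerate otherwise)")
  if (length(truth$informative_indices) &&
      max(truth$informative_indices) > mask$n_voxels)
    stop("informative_indices exceed the number of mask voxels")
  set.seed(seed)
  n <- 2L * n_per_group
  maps <- matrix(0, n, mask$n_voxels)
  noise <- masked_noise_sampler(mask, truth$smooth_fwhm)
  for (s in seq_len(n)) maps[s, ] <- truth$noise_sd * noise()
  shift <- numeric(mask$n_voxels)
  shift[truth$informative_indices] <- truth$effect_sizes * truth$noise_sd
  maps[seq_len(n_per_group), ] <-
    maps[seq_len(n_per_group), , drop = FALSE] +
    matrix(shift, n_per_group, mask$n_voxels, byrow = TRUE)
  labels <- factor(rep(c("chronic", "normal"), each = n_per_group),
                   levels = c("normal", "chronic"))
  tab <- simulate_cohort_table(n_per_group, seed = seed + 1L)
  rownames(maps) <- tab$id
  structure(list(maps = maps, labels = labels, table = tab,
                 mask = mask, truth = truth, seed = as.integer(seed)),
            class = "contrast_cohort")
}

# Returns a closure drawing one unit-variance smoothed noise field restricted
# to the mask voxels. Noise is generated on the mask bounding box padded by
# the kernel support, which is equivalent to full-grid generation for the
# voxels that matter.
masked_noise_sampler <- function(mask, fwhm_mm) {
  voxel_mm <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  if (fwhm_mm > 0) {
    half <- vapply(1:3, function(ax)
      (length(gauss_kernel_1d(fwhm_mm, voxel_mm[ax])) - 1L) %/% 2L,
      integer(1L))
  } else half <- c(0L, 0L, 0L)
  lo <- pmax(apply(mask$voxel_index, 2L, min) - half, 0L)
  hi <- pmin(apply(mask$voxel_index, 2L, max) + half, mask$shape - 1L)
  box <- hi - lo + 1L
  vi <- sweep(mask$voxel_index, 2L, lo)          # 0-based within box
  lin <- vi[, 1L] + box[1L] * (vi[, 2L] + box[2L] * vi[, 3L]) + 1L
  if (fwhm_mm > 0) {
    sd_map <- smoothed_noise_sd(box, fwhm_mm, voxel_mm)
    function() {
      field <- array(rnorm(prod(box)), dim = box)
      field <- gaussian_smooth_3d(field, fwhm_mm, voxel_mm)
      (field / sd_map)[lin]
    }
  } else {
    function() rnorm(length(lin))
  }
}

#' Simulate a cohort demographics table
#'
#' Draws a demographics table with the marginal structure of a 26-subject
#' chronic low-back-pain case/control study: ages roughly uniform over 38-65
#' years, sex about 9 female / 4 male per 13, handedness 10 right / 2 left /
#' 1 ambidextrous, ethnicity 10 / 3, pain thresholds log-normal around
#' 0.7 mA, and (chronic group only) years since onset between 0.5 and about
#' 5. These covariates feed the companion demographic statistics, never the
#' decoder.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `group`, `age`, `sex`, `hand`,
#'   `ethnicity`, `threshold_mA`, `duration_years` (NA for controls).
#' @export
simulate_cohort_table <- function(n_per_group = 13L, seed = 1L) {
  set.seed(seed)
  n_per_group <- as.integer(n_per_group)
  marg <- function(props) {  # counts per group following fixed proportions
    k <- round(props * n_per_group)
    k[1L] <- n_per_group - sum(k[-1L])
    k
  }
  one_group <- function(prefix, chronic) {
    sex <- sample(rep(c("F", "M"), marg(c(9, 4) / 13)))
    hand <- sample(rep(c("R", "L", "A"), marg(c(10, 2, 1) / 13)))
    eth <- sample(rep(c("C", "B"), marg(c(10, 3) / 13)))
    thr <- round(exp(rnorm(n_per_group, log(0.7), 0.4)) * 10) / 10
    thr <- pmax(thr, 0.1)
    dur <- if (chronic) {
      pmax(round(exp(rnorm(n_per_group, log(2), 0.8)) * 2) / 2, 0.5)
    } else rep(NA_real_, n_per_group)
    data.frame(id = sprintf("%s%02d", prefix, seq_len(n_per_group)),
               group = if (chronic) "chronic" else "normal",
               age = sample(38:65, n_per_group, replace = TRUE),
               sex = sex, hand = hand, ethnicity = eth,
               threshold_mA = thr, duration_years = dur,
               stringsAsFactors = FALSE)
  }
  rbind(one_group("CP", TRUE), one_group("NC", FALSE))
}

#' Simulate rigid-body realignment parameter traces
#'
#' Random-walk motion traces (3 translations in mm, 3 rotations in radians)
#' per subject, used to exercise the head-motion summary statistics.
#'
#' @param n_subjects Number of subjects.
#' @param n_scans Scans per subject.
#' @param step_sd_mm SD of scan-to-scan translation increments (mm).
#' @param step_sd_rad SD of scan-to-scan rotation increments (radians).
#' @param seed Integer seed.
#' @return List of `n_scans` x 6 matrices with columns
#'   `trans_x, trans_y, trans_z, pitch, roll, yaw`.
#' @export
simulate_motion_params <- function(n_subjects, n_scans = 172L,
                                   step_sd_mm = 0.05,
                                   step_sd_rad = 5e-4, seed = 1L) {
  set.seed(seed)
  sds <- c(rep(step_sd_mm, 3), rep(step_sd_rad, 3))
  lapply(seq_len(n_subjects), function(s) {
    m <- vapply(sds, function(sd) cumsum(rnorm(n_scans, 0, sd)),
                numeric(n_scans))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "pitch", "roll", "yaw")
    m
  })
}

#' @export
print.contrast_cohort <- function(x, ...) {
  cat(sprintf("contrast_cohort: %d subjects (%s) x %d mask voxels\n",
              nrow(x$maps), paste(table(x$labels), collapse = "+"),
              ncol(x$maps)))
  cat(sprintf("  informative voxels: %d; noise sd %.3g; smoothing FWHM %g mm\n",
              length(x$truth$informative_indices), x$truth$noise_sd,
              x$truth$smooth_fwhm))
  invisible(x)
}
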