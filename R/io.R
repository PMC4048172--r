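#' Write and read masks as NIfTI-1
#'
#' The mask grid is stored as a 0/1 volume with the affine in the sform.
#'
#' @param mask A `mask_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.numeric(mask$grid), dim = mask$shape))
  img <- set_affine(img, mask$affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- array(as.array(img) > 0.5, dim = dim(img))
  aff <- unclass(RNifti::xform(img))
  shape <- dim(grid)
  inside <- which(grid)
  vi <- arrayInd(inside, shape) - 1L
  mm <- t(aff %*% rbind(t(vi), 1))[, 1:3, drop = FALSE]
  structure(list(grid = grid, affine = structure(aff, imagedim = NULL),
                 n_voxels = length(inside),
                 labels = rep(NA_character_, length(inside)),
                 voxel_index = vi, coords_mm = mm, shape = shape),
            class = "mask_volume")
}

#' Write and read masked contrast values as NIfTI-1
#'
#' Values are embedded into the mask grid (zero outside the mask) on write;
#' on read the volume's affine must match the mask's, otherwise an error
#' names both files (no silent resampling).
#'
#' @param values Per-mask-voxel contrast values.
#' @param mask The `mask_volume` defining voxel order and affine.
#' @param path NIfTI path.
#' @return `path` (write) or numeric vector over mask voxels (read).
#' @export
write_contrast_nifti <- function(values, mask, path) {
  stopifnot(inherits(mask, "mask_volume"), length(values) == mask$n_voxels)
  vol <- array(0, dim = mask$shape)
  vol[mask$grid] <- values
  img <- set_affine(RNifti::asNifti(vol), mask$affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_contrast_nifti
#' @param mask_path Optional path of the mask file, used in error messages.
#' @export
read_contrast_nifti <- function(path, mask, mask_path = "<mask>") {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  if (max(abs(aff - mask$affine)) > 1e-4)
    stop("affine mismatch between contrast volume '", path,
         "' and mask '", mask_path, "'")
  as.array(img)[mask$grid]
}

set_affine <- function(img, affine) {
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

#' Write a cohort to disk
#'
#' Emits one contrast NIfTI per subject, the mask volume, the demographics
#' CSV and the ground truth as JSON.
#'
#' @param cohort A `contrast_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "contrast_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_path <- file.path(dir, "mask.nii.gz")
  write_mask_nifti(cohort$mask, mask_path)
  con_paths <- file.path(dir, sprintf("con_%s.nii.gz", cohort$table$id))
  for (i in seq_len(nrow(cohort$maps)))
    write_contrast_nifti(cohort$maps[i, ], cohort$mask, con_paths[i])
  table_path <- file.path(dir, "cohort.csv")
  write.csv(cohort$table, table_path, row.names = FALSE)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(unclass(cohort$truth), truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(mask = mask_path, contrasts = con_paths,
                 table = table_path, truth = truth_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `mask.nii.gz`, `con_*.nii.gz`, `cohort.csv`
#'   and `ground_truth.json`.
#' @return A `contrast_cohort`.
#' @export
read_cohort <- function(dir) {
  mask_path <- file.path(dir, "mask.nii.gz")
  mask <- read_mask_nifti(mask_path)
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  maps <- t(vapply(tab$id, function(id)
    read_contrast_nifti(file.path(dir, sprintf("con_%s.nii.gz", id)),
                        mask, mask_path),
    numeric(mask$n_voxels)))
  tj <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  truth <- ground_truth(tj$informative_indices %||% integer(0),
                        tj$effect_sizes %||% 0, tj$noise_sd, tj$smooth_fwhm,
                        tj$seed)
  labels <- factor(tab$group, levels = c("normal", "chronic"))
  structure(list(maps = maps, labels = labels, table = tab,
                 mask = mask, truth = truth),
            class = "contrast_cohort")
}

#' Serialize a fitted decoder to JSON
#'
#' @param model An `slr_model`.
#' @param path Output path.
#' @return `path`, invisibly; `read_slr_model()` restores the object.
#' @export
write_slr_model <- function(model, path) {
  stopifnot(inherits(model, "slr_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slr_model
#' @export
read_slr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$retained <- as.integer(obj$retained %||% integer(0))
  for (f in c("w", "alpha", "center", "scale"))
    obj[[f]] <- as.numeric(obj[[f]] %||% numeric(0))
  structure(obj, class = "slr_model")
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration; unknown top-level keys are rejected so
#' typos fail loudly.
#'
#' @param path YAML file.
#' @return Named list of settings merged over the defaults.
#' @export
read_config <- function(path) {
  defaults <- default_config()
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

default_config <- function() {
  list(output_dir = "results",
       n_per_group = 13L,
       n_informative = 3L,
       effect_size = 2,
       noise_sd = 1,
       smooth_fwhm = 8,
       seed = 1L,
       permutations = 1000L,
       fdr_q = 0.05,
       hp_cutoff_s = 128,
       tr = 3.67, n_scans_per_run = 86L, n_runs = 2L,
       block_s = 14, n_cycles = 5L,
       alpha_init = 1, prune_threshold = 1e8,
       max_iter = 500L, tol = 1e-6, standardize = TRUE)
}

#' Assemble a reproducible run report
#'
#' Bundles the configuration echo, software version and the numeric results
#' of a decoding run; rerunning with the same configuration and seed
#' reproduces every numeric field.
#'
#' @param config Configuration list (echoed verbatim).
#' @param performance A `performance_report`, or NULL.
#' @param permutation A `permutation_null`, or NULL.
#' @param features A `feature_significance`, or NULL.
#' @param timings Named numeric vector of per-stage seconds, or NULL.
#' @return List of class `run_report`; write with [write_run_report()].
#' @export
run_report <- function(config, performance = NULL, permutation = NULL,
                       features = NULL, timings = NULL) {
  rep <- list(
    package = "painmvpa",
    version = as.character(utils::packageVersion("painmvpa")),
    config = config,
    config_hash = config_hash(config),
    timings = as.list(timings))
  if (!is.null(performance))
    rep$performance <- unclass(performance)[c(
      "accuracy", "sensitivity", "specificity", "ppv", "npv", "d_prime",
      "posterior_mean", "posterior_interval", "mean_n_features")]
  if (!is.null(permutation))
    rep$permutation <- list(observed = permutation$observed,
                            B = permutation$B,
                            p_value = permutation$p_value)
  if (!is.null(features))
    rep$features <- features$table[features$table$count > 0L, ]
  structure(rep, class = "run_report")
}

# order-independent hash of the configuration, for provenance
config_hash <- function(config) {
  s <- paste(names(config)[order(names(config))],
             vapply(config[order(names(config))],
                    function(v) paste(format(v, digits = 15),
                                      collapse = ","),
                    character(1L)),
             sep = "=", collapse = ";")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1; all
  # intermediates stay exactly representable in doubles
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 131 + cc) %% 2147483647
  sprintf("%08x", h)
}

#' @rdname run_report
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Demographics table of the 26-subject chronic low-back-pain cohort
#'
#' The printed case/control demographics (13 chronic low-back-pain subjects,
#' 13 controls): age, sex, handedness, ethnicity, pain-threshold stimulation
#' level (mA) and, for the chronic group, years since onset. Consumed by
#' the companion demographic statistics.
#'
#' @return Data frame with the [simulate_cohort_table()] columns.
#' @export
study_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "painmvpa")
  read.csv(path, stringsAsFactors = FALSE)
}
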