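#!/usr/bin/env Rscript
# Stage 3: train and evaluate the sparse decoder.
#
# Loads the cohort from stage 1 (regenerating it if absent), runs
# leave-one-out cross-validation of the ARD sparse logistic regression,
# assesses significance of the accuracy by permutation, and locates the
# voxels the decoder relies on via selection-count permutation FDR.
# Outputs: a one-row performance table, the permutation summary, and a
# selected-voxel table with MNI coordinates.

suppressPackageStartupMessages(library(painmvpa))

seed <- 20140608L
B <- 99L    # permutations; the emulated study used 1000 -- raise for a
            # finer p-value floor (each permutation reruns the full LOOCV)
out_dir <- "results/decode"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- if (dir.exists("results/cohort")) {
  message("reading the stage-1 cohort ...")
  read_cohort("results/cohort")
} else {
  message("stage-1 output not found; simulating the cohort now ...")
  source("analysis/01_simulate_cohort.R")
  read_cohort("results/cohort")
}

message("leave-one-out cross-validation (26 folds) ...")
cv <- loocv_decode(cohort)
perf <- performance_metrics(cv)
print(perf)

perf_row <- data.frame(
  accuracy_pct = 100 * perf$accuracy,
  sensitivity_pct = 100 * perf$sensitivity,
  specificity_pct = 100 * perf$specificity,
  ppv_pct = 100 * perf$ppv, npv_pct = 100 * perf$npv,
  posterior_mean_pct = 100 * perf$posterior_mean,
  posterior_low_pct = 100 * perf$posterior_interval[1],
  posterior_high_pct = 100 * perf$posterior_interval[2],
  d_prime = perf$d_prime, mean_n_features = perf$mean_n_features)
write.csv(perf_row, file.path(out_dir, "performance.csv"),
          row.names = FALSE)

message("permutation test (B = ", B, ") ...")
pt <- permutation_test_accuracy(cohort, B = B, seed = seed)
print(pt)
writeLines(jsonlite::toJSON(list(observed = pt$observed, B = pt$B,
                                 p_value = pt$p_value), auto_unbox = TRUE),
           file.path(out_dir, "permutation.json"))

message("selection-count significance (pooled null, BH-FDR 0.05) ...")
fs <- feature_selection_significance(cv, pt, q = 0.05)
sel <- fs$table[fs$table$count > 0L, ]
mm <- cohort$mask$coords_mm[sel$voxel, , drop = FALSE]
sel$x_mm <- mm[, 1]; sel$y_mm <- mm[, 2]; sel$z_mm <- mm[, 3]
sel <- sel[order(-sel$count), ]
write.csv(sel, file.path(out_dir, "selected_voxels.csv"),
          row.names = FALSE)
message(sprintf("  %d voxel(s) ever selected; %d significant at FDR 0.05",
                nrow(sel), sum(sel$flag)))
message("  planted voxels were at indices ",
        paste(cohort$truth$informative_indices, collapse = ", "))
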