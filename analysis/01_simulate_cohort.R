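#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Builds the five-region pain mask (~6686 voxels at 2 mm), plants three
# informative voxels -- two with chronic < normal in S1, one with
# chronic > normal in IPC, |d| = 2 -- and draws 13 chronic + 13 control
# contrast maps with spatially smoothed unit-variance noise. Everything is
# written under results/cohort/ as NIfTI + CSV + JSON.

suppressPackageStartupMessages(library(painmvpa))

seed <- 20140606L
out_dir <- "results/cohort"

message("building the five-region pain mask ...")
mask <- default_pain_mask()
message(sprintf("  %d voxels across %s", mask$n_voxels,
                paste(names(table(mask$labels)), collapse = ", ")))

set.seed(seed)
idx <- c(sample(which(mask$labels == "S1"), 2L),
         sample(which(mask$labels == "IPC"), 1L))
truth <- ground_truth(idx, c(-2, -2, 2), noise_sd = 1, smooth_fwhm = 8,
                      seed = seed)
message(sprintf("  informative voxels at MNI %s (effects %s)",
                paste(apply(mask$coords_mm[idx, ], 1, paste,
                            collapse = ","), collapse = " | "),
                paste(truth$effect_sizes, collapse = ", ")))

cohort <- simulate_contrast_cohort(mask, truth, n_per_group = 13L)
print(cohort)

paths <- write_cohort(cohort, out_dir)
message(sprintf("wrote %d contrast volumes, mask, cohort table and ground ",
                length(paths$contrasts)),
        "truth under ", out_dir)
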