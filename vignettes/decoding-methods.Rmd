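---
title: "Decoding chronic pain from fMRI contrast maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding chronic pain from fMRI contrast maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmvpa)
```

`painmvpa` implements a complete two-group fMRI decoding study in
simulation: a cohort of chronic low-back-pain patients and matched controls
each receives blocks of painful electrical stimulation in the scanner, a
first-level GLM reduces each subject's BOLD series to one
stimulation-versus-rest contrast map over a mask of pain-processing regions,
and a sparse Bayesian classifier is asked to tell patients from controls
from those maps alone. Because no subject-level data from such studies is
publicly available, the package ships a synthetic-cohort generator whose
outputs have the statistical structure the decoding analysis assumes; every
inferential procedure is then exercised against cohorts whose ground truth
is known.

## The synthetic cohort

A cohort consists of `n` subjects per group (default 13 + 13). Each
subject's "contrast map" is one value per voxel of an analysis mask.

**Mask.** `default_pain_mask()` places five spheres at left-lateralized
coordinates for primary and secondary somatosensory cortex, inferior
parietal cortex, insula and anterior cingulate cortex on the standard
2 mm MNI grid, sized to contain 6785 voxels — within 1.5% of the 6686-voxel
pain-region mask such studies typically derive from an anatomical atlas.
The sphere radius (13.6 mm) was fixed once from that voxel-count target
and is not otherwise meaningful.

**Noise.** Contrast noise is Gaussian, spatially smoothed with an 8 mm
FWHM kernel — the same width used for spatial smoothing of the images in
the emulated preprocessing — and rescaled so that the marginal standard
deviation equals `noise_sd` *exactly at every voxel* (the rescaling uses
the analytically propagated per-voxel variance of the smoothed field,
including edge attenuation). This makes planted effect sizes interpretable
as Cohen's d.

**Signal.** `ground_truth()` lists informative voxels and signed effects in
d units. The default study configuration plants three informative voxels:
two with chronic < normal in S1 and one with chronic > normal in IPC,
|d| = 2, mirroring the sign structure reported for the regions that drive
decoding in this literature. Effects are added at single voxels (they are
not smoothed); the noise field carries the spatial correlation.

**Demographics.** `simulate_cohort_table()` draws age, sex, handedness,
ethnicity, pain threshold (log-normal around 0.7 mA) and, for patients,
years since onset, matching the marginal structure of the published
26-subject table. These covariates feed only the companion statistics,
never the decoder. The published table itself ships as
`study_demographics()` since printed tables are data.

What the generator does *not* emulate: scanner artifacts, motion-correlated
signal, physiological noise, anatomical variability, and any spatial
structure in the *signal* beyond single voxels. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
model, not decoding performance on real scanners.

## First-level GLM

`simulate_bold_cohort()` generates per-voxel series
`baseline + responsiveness × (boxcar ⊛ HRF) + drift + AR(1) noise` for the
block design (14 s on / 14 s off × 5 cycles, TR 3.67 s, 86 scans × 2 runs).
The GLM stage recovers the contrast:

- **Task regressor**: the boxcar sampled at scan times, convolved with the
  canonical double-gamma HRF (response gamma shape 6, undershoot shape 16,
  ratio 6; peak at 5 s), one shared regressor across runs.
- **Drift**: per-run orthonormal DCT basis with
  `K = floor(2·n·TR/cutoff) + 1` columns (cutoff 128 s ⇒ K = 5 for 86
  scans); the constant is carried by per-run intercepts, so high-pass
  filtering is embedded in the design as an equivalent projection rather
  than applied beforehand.
- **Serial correlation**: a two-pass fit. OLS residuals give a lag-1
  autocorrelation pooled over all mask voxels (one global φ, the
  conventional choice — per-voxel estimates at 172 scans are too noisy).
  Because OLS residuals attenuate autocorrelation (the drift columns absorb
  exactly the low frequencies where an AR(1) process carries its
  covariance), the raw pooled ratio is mapped through the design's expected
  attenuation curve — both traces involved are polynomials in φ through the
  lag sums of the residual-forming matrix, so the inversion is cheap and
  exact in expectation. Data and design are then whitened by the AR(1)
  inverse square root within runs and refit. On simulated φ = 0.3 data the
  de-biased estimate is centered on 0.30 (raw: ≈ 0.21).
- **Contrast**: weight +1 on the task regressor — stimulation minus rest,
  rest being baseline. With zero noise the pipeline returns the programmed
  responsiveness exactly (round-trip checked to 1e-8).

## The sparse decoder

The classifier is Bayesian logistic regression with automatic relevance
determination: each weight `w_i` has a zero-mean Gaussian prior with its
own precision `α_i`. Fitting alternates

1. Newton-Raphson to the MAP weights at fixed α (with step halving);
2. the Laplace posterior covariance `S = H⁻¹` at the MAP;
3. MacKay evidence updates `α_i ← γ_i / w_i²`, `γ_i = 1 − α_i S_ii`;
4. pruning of features with `α_i > 10⁸` (pruned features never re-enter),

until every surviving weight's relative change falls below `tol = 1e-6`.
The bias has a fixed broad prior (precision 1e-10) and is never pruned.
Most precisions diverge, so the model that emerges uses only a handful of
voxels — feature selection and training in one step. On the full-scale
simulated study (26 subjects, ~6700 voxels, three planted voxels at d = 2)
fits retain 3 features on average, in line with the 2.85 reported for the
decoder this emulates.

Numerical choices worth knowing:

- For `p ≫ n` the Newton step and the diagonal of `S` are computed through
  the Woodbury identity (`O(p·n²)` per sweep); once the active set is
  small, a direct Cholesky path takes over. `γ_i` is computed as
  `α_i·q_i` in the Woodbury form, avoiding the `1/α_i − S_ii` cancellation
  for diverging precisions.
- A feature whose precision is rising while its weight sits below 0.1% of
  the largest weight is on a monotone geometric path to the threshold and
  contributes nothing to predictions; it is pruned immediately rather than
  iterated out one evidence update at a time. (Spot checks against
  uncapped runs show identical surviving weights to 4+ decimals.)
- Features are z-scored with *training-fold* statistics; held-out subjects
  are transformed with the same constants. Zero-variance features are
  dropped with a warning.
- Predicted class is 1 (chronic) iff the predicted probability exceeds
  0.5; exactly 0.5 goes to the normal class — an arbitrary but fixed and
  documented tie rule.
- Non-convergence within `max_iter = 500` returns the current model
  flagged `converged = FALSE` rather than failing; leave-one-out runs
  propagate the flag per fold.

## Evaluation and inference

**LOOCV.** One fold per subject; each decoder is trained on the other 25
and tested on the held-out map. Accuracy, sensitivity, specificity, PPV,
NPV and d′ are read off the pooled confusion matrix. For d′, rates of
exactly 0 or 1 are moved by `1/(2N)` before the inverse-normal transform
(switchable). Note that the standard formula gives
`2·Φ⁻¹(12/13) = 2.852` for the 12-of-13 benchmark; published values for
this quantity sometimes differ slightly (e.g. 2.924), which is not
reproducible from the stated convention and is not used as a target here.

**Posterior accuracy.** With `k` of `n` correct under a uniform prior, the
accuracy posterior is Beta(1+k, 1+n−k); the central 95% interval serves as
a confidence interval. For 24/26 this gives [75.7%, 97.6%]; the interval
narrows as n grows at fixed k/n.

**Permutation test.** `B` relabelings (group sizes preserved), each
rerunning the *full* LOOCV; `p = (1 + #{null ≥ observed})/(B + 1)` — the
add-one estimator avoids zero p-values. Per-permutation sub-seeds are
drawn once from the master seed, so results are reproducible and
parallelizable.

**Selected-voxel inference.** Each voxel's selection count across the 26
folds is compared with selection counts from the permuted reruns. The
default pools null counts across voxels and permutations and applies
Benjamini–Hochberg FDR at q = 0.05 (per-voxel nulls are too sparse at
B ≤ 1000); a max-statistic (family-wise) mode is available as a flag.

**Companion statistics.** Voxelwise pooled-variance t-maps with BH-FDR;
pain-threshold weighting implemented as per-subject multiplicative scaling
of the contrast before the group test (the loosest but most direct reading
of "weighted by threshold"); duration correlation as Pearson r converted to
t with n−2 dof; small-volume correction as BH-FDR restricted to an 8 mm
sphere; Wilcoxon rank-sum with exact enumeration up to combined n = 12 and
a tie-corrected, continuity-corrected normal approximation above;
Lilliefors-style normality (KS statistic against a normal with estimated
parameters, Monte-Carlo p); Rosner's normal-approximation power for two
proportions with both rejection tails accumulated; and head-motion
summaries (summed scan-to-scan |Δ| or total within-session deviation per
realignment parameter, compared by pooled t-tests).

## Monte-Carlo problem sizes

Simulation-based checks in the test suite use problem sizes chosen to make
their Monte-Carlo error small relative to the asserted bands while keeping
the full suite desk-scale: the d = 2 parameter-recovery study runs 50
cohorts at the full ~6700-voxel mask; null-cohort calibration runs 100
cohorts × 99 permutations on `scatter_mask()`, an 18-voxel lattice whose
spacing exceeds the smoothing kernel — type-I error and exchangeability are
dimension-free, and near-duplicate voxels would only slow the decoder
without changing the question being asked. Smaller property checks use
30–60 replicates each.

## Known limitations and honest findings

Two empirical properties of leave-one-out evaluation with this decoder are
worth stating plainly, because the package's own simulations exhibit them:

- **Null LOOCV accuracy sits below 50%.** With balanced groups, every
  training fold is 12-vs-13; the intercept (and, mildly, fold-wise
  centering) tracks the majority class, which is by construction the class
  *opposite* the held-out subject. When the decoder finds no signal this
  produces systematically wrong predictions — the well-known leave-one-out
  pessimism. Across 100 null cohorts on the independent-voxel lattice the
  mean accuracy is 0.472 (SD 0.16) — measurably below 0.50, and further
  below it on masks whose voxels are near-duplicates (where fits often
  collapse to the intercept). The permutation test is unaffected
  (observed and null accuracies share the bias; measured rejection rate
  4% at α = 0.05 with B = 99), which is exactly why significance should
  be assessed by permutation rather than against a nominal 50% chance
  level.
- **d = 2 at three voxels among ~6700 is not reliably decoded at ≥ 90%.**
  The informative voxels' expected |t| ≈ 5.1 overlaps the maximum spurious
  |t| (≈ 4–5) over the mask, so feature selection occasionally locks onto
  noise; across 50 cohorts the mean LOOCV accuracy is 0.86 (quartiles
  0.81–0.95) with 44% of cohorts at ≥ 90%. Larger effects, more
  informative voxels, or larger cohorts move this rapidly toward ceiling
  (see the effect-monotonicity test).

- **Selection-count nulls are long-tailed.** Because leave-one-out folds
  share 24 of 25 training subjects, a decoder fit to *permuted* labels
  also selects some (spurious) voxel consistently across folds; null
  selection counts of 20+ out of 26 occur for a fraction of a percent of
  voxel–permutation pairs. Planted voxels still attain the smallest
  p-values by a wide margin, but count-based FDR flags are conservative
  under the whole-cohort permutation scheme implemented here (one shuffle
  per permutation, maintained across folds). Low null maxima would
  require an independent shuffle per fold, a different — and less
  exchangeability-faithful — null.

Other limitations: the ARD fixed point at n = 26 retains a few spurious
features on pure-noise data (≈ 6 of 100 independent candidates) — sparse,
but not the 1–2 one might hope for; no slice-timing, realignment,
normalization or smoothing is modeled (only realignment *summaries* are
compared statistically); no multinomial or kernel extension of the
decoder; no cluster-extent or random-field correction (voxel-level FDR
only, as in the emulated analysis).
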