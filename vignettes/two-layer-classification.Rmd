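---
title: "Two-layer classification of hearing impairment from sMRI and fMRI"
author: "hearclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer classification of hearing impairment from sMRI and fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearclass)
```

## The problem and the model

Congenital sensori-neural hearing loss alters both brain structure and
auditory-task activation in infants. `hearclass` classifies
hearing-impaired (HI) versus normal-hearing (NH) subjects from two
inputs per subject, both assumed already spatially normalized to a
common voxel grid: a T1-like structural volume and three functional
contrast maps (speech vs. silence, speech vs. tones, tones vs.
silence). Two very different feature extractors feed a small stacked
model:

1. a **structural arm** that scores blob-like local image structure
   (SIFT keypoints) by how much more often similar features occur in
   patient brains than in control brains;
2. a **functional arm** that represents each subject as mean contrast
   values over a bag-of-words dictionary of activation regions; and
3. a **second layer** — a linear SVM with C = 1 over the two scalar
   scores — that fuses them.

The rationale for stacking rather than concatenation: a subject's SIFT
features form a *set* of variable size, not a fixed-length vector, so
the structural information only becomes a feature ("Csum") after its
own classification step. The two arms also make different kinds of
errors, which is exactly the situation where fusing decision scores
can beat either arm.

## Structural arm

The volume is tiled into cubes of side 20 (boundary cubes keep the
remainder; the full 157 × 189 × 136 template grid yields 560 cubes)
and each cube is sliced along the axial, coronal and sagittal axes.
Cube-wise processing keeps the pairwise feature comparison tractable
and localizes every comparison anatomically; the cost is that a
feature near a cube border cannot see similar features in the
neighboring cube, which mildly degrades likelihood scores.

Our axis convention: array axes (i, j, k), 1-based; axial slices fix
k, coronal fix j, sagittal fix i. Any fixed convention works as long
as training and prediction share it.

**SIFT.** No R package provides a 2D SIFT implementation, so the
package carries a standard one (difference-of-Gaussian scale space,
strict 26-neighbor extrema, quadratic sub-pixel refinement, contrast
and edge rejection, dominant-orientation assignment, the 4 × 4 × 8
unit-normalized descriptor). Detector thresholds are exposed in
`sift_params()` because 20 × 20 slices are far smaller than
photographic images; the default contrast threshold (0.01) suits
volumes on a roughly unit intensity scale. Each keypoint becomes a
133-number feature: 3D center (via the slice-to-volume mapping),
scale, orientation, 128 appearance numbers.

**Similarity and likelihood.** The similar-feature set uses four
strict inequalities with defaults ε_x = 0.5, ε_σ = 2/3, ε_o = π/2,
ε_a = 0.45. Two reading choices are deliberate:

* Δσ is the *absolute* log scale ratio. A signed ratio under a
  positive threshold would accept arbitrarily small σ_j, making the
  2/3 threshold meaningless; the absolute value restores
  scale-symmetry.
* Δx is normalized by the *query's* scale, as defined, so similarity
  is asymmetric and S_i is per query.

The likelihood L_i = ln[(|S_i∩P|/N_P)/(|S_i∩C|/N_C)] requires support:
we read the support condition as |S_i| ≥ N_P + N_C (about one similar
feature per training brain), exposed as `support_min`. Empty
intersections are handled by additive smoothing with pseudocount
α = 1 on both counts and both brain totals; α = 0 reproduces the raw
ratio with infinities capped at ±50. Smoothing is symmetric, so
swapping the patient and control roles negates every nonzero score.
Labels: +1 if L_i > ε_l, −1 if L_i < −ε_l, else 0 (noise), with
ε_l = 0.9.

**Per-cube classifiers and Csum.** One linear 3-class SVM per (cube,
orientation) learns the labels from standardized 133-vectors. The
multiclass scheme is one-vs-rest (the underlying libsvm default of
one-vs-one voting does not expose per-class scores cleanly); groups
with a single training label get a constant predictor. A subject's
Csum is the sum of predicted labels over all its features (noise
contributes 0; untrained groups are skipped), and HI is called when
Csum > ε_s strictly, ε_s being the smallest threshold equalizing
training FPR and FNR (candidates are midpoints between consecutive
distinct training scores).

`tune_smri_thresholds()` reproduces the grid search over
ε_o ∈ {π/4, 2π/4, 3π/4}, ε_a ∈ {0.30,...,0.50} and ε_l ∈ {0.1,...,1.2}
as an optional routine; the defaults are the chosen values and nothing
in the package runs the search implicitly.

## Functional arm

Per contrast map, positive and negative voxels are ranked separately
and the top 5% of each sign kept — computed over non-zero voxels, with
ties at the cutoff broken by voxel index; an optional mask restricts
the eligible voxels. Selected voxels are componentized under
26-connectivity with the two signs componentized separately (a mixed
ROI would cancel its own signal when averaged). Each ROI is a
dictionary word; each subject is the vector of mean contrast values
over every word, concatenated across the three contrasts in a fixed
recorded order (contrast, then subject, then component).

**Merging.** Columns are clustered by average linkage on Euclidean
distance across subjects and the dendrogram is cut with an
inconsistency coefficient of 0.01 (depth 2); clusters are replaced by
their member means. One numerical convention matters: we compute the
inconsistency statistic with leaves counted as zero-height joins.
Under the link-only convention every leaf–leaf join has coefficient 0
and *any* closest pair of columns would merge regardless of distance;
with leaves included, a positive-height join of two singletons has
coefficient 2/√3 ≈ 1.155 independent of its height, so any cutoff in
(0, 1.15) merges exact redundancy (height ≈ 0) and nothing else. That
also explains why the clustering is insensitive to the cutoff over a
wide low range.

**Sedation.** Sedation method (3 levels) is appended as a one-hot
triple, since different sedatives attenuate the BOLD response
differently.

**CFS.** Subset merit M_S = k·r̄_cf / sqrt(k + k(k−1)·r̄_ff) uses
Pearson correlations of the continuous features against ±1 labels
(absolute values; `correlation = "spearman"` is available as a knob;
zero-variance features count 0). The search is best-first from the
empty set: successors flip one feature, an open list ordered by merit
provides backtracking, and the search stops after 5 consecutive
non-improving expansions (plus a hard cap, default 200, as a safety
valve). On ≤ 15-feature pools the search provably matches exhaustive
subset enumeration in our tests. A linear SVM (C = 1) on the selected,
standardized features yields the decision score; HI iff score ≥ 0
(inclusive). Feature importance across folds is
I_f = Σ_i σ_i |w_if|, and a merged ROI inherits its joint feature's
importance.

**Dictionary scope.** By default the dictionary is built from *all*
available subjects, including the one being tested in a fold
(`dictionary_scope = "all_subjects"`): the dictionary is treated as a
feature pool, not a trained quantity. The `"train_only"` variant
rebuilds the dictionary per fold from training subjects and applies it
to the held-out subject. One documented consequence of the default: an
ROI delineated from the test subject's own top-5% voxels has, for that
subject, a selection-inflated mean (its own extreme region), which
nudges held-out scores upward regardless of group; at very small n
this can cost a fold. The `"train_only"` scope avoids the effect at
the price of a weaker feature pool.

## Second layer and evaluation

The two in-sample training scores feed a linear SVM with C = 1 in 2D
(no standardization: the space is tiny and the constant is part of the
protocol); prediction is y = w₁·Csum + w₂·fMRI_score + bias, HI iff
y ≥ 0. First-layer training scores are in-sample by design, matching
the protocol the model defines; a nested (out-of-fold) variant would
reduce stacking optimism but is deliberately not the default.

Leave-one-out cross-validation retrains everything per fold (ε_s on
training Csum; ε_f = ε_i = 0). The summary reports, per classifier:
specificity, sensitivity and accuracy of the training-derived
thresholds on the held-out subjects; AUC (Mann–Whitney form —
identical to the trapezoidal ROC area, ties counted half); and the
EER accuracy, whose threshold is chosen purely on the test scores to
minimize |FPR − FNR| (candidates: midpoints between consecutive
distinct scores plus sentinels; ties take the lower threshold; the
accuracy reported is 1 − (FPR+FNR)/2). Feature-selection stability is
the mean pairwise Jaccard similarity of per-fold selections; two empty
selections count as identical (similarity 1).

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions for every test:

* **Anatomy**: a smooth bright-center background, fixed shared blobs
  (amplitude 0.4), and `n_discriminative_blobs` sites at cube centers
  whose amplitude is `blob_base` (0.15) for NH and
  `blob_base + blob_effect` for HI, plus i.i.d. voxel noise
  (sd 0.05). Sites sit at cube centers so they survive partitioning —
  SIFT detects exactly this kind of blob-like structure. Amplitudes
  are in the volume's arbitrary intensity units (unit-scale
  background).
* **Contrast maps**: spatially coarse Gaussian noise (block size 5,
  sd 4 × `noise_sd`) rather than i.i.d. voxel noise — real Z-maps are
  smooth, and an i.i.d. field would shatter the top-5% excursion set
  into thousands of singleton ROIs; the coarse field yields a
  realistic dictionary of tens of ROIs per map. On top: fixed
  activation sites per contrast (signs alternating) with amplitude
  `activation_base` (0.6) for NH and `+ activation_effect` for HI,
  and 2 random nuisance activations per map per subject.
* **Sedation**: randomized blocks within each group — random order,
  near-uniform marginal, and structurally confound-free, which
  matters at n = 6 where per-subject uniform draws regularly produce
  a perfect sedation–group confound that CFS would (correctly) latch
  onto. `sedation_confounded = TRUE` couples sedation to group on
  purpose.
* The default grid is 40 × 40 × 20 (4 cubes; the full 157 × 189 × 136
  grid is supported) — chosen so that a full LOOCV on a dozen
  subjects runs in seconds to minutes on one core.

What the generator does *not* emulate: MR physics, motion/ghosting,
registration error, pediatric anatomy, GLM estimation of contrast
maps (maps are generated directly in their statistical role).
Passing tests therefore demonstrate the *pipeline's* correctness and
its signal-vs-null behavior, not clinical performance.

## Study conditions used by the test suite and acceptance script

* **Null calibration**: 10 cohorts of 6 + 6 subjects with both effects
  0; the mean combined LOOCV AUC should sit within ~3 standard errors
  of 0.5. Cohorts are deliberately not smaller: with 4 + 4 subjects
  LOOCV itself is pessimistically biased under the null (removing one
  of four HI subjects shifts the training prior by 25%,
  anti-correlating held-out scores), an artifact of extreme sample
  size rather than of the method.
* **Overwhelming effect**: 3 + 3 subjects, `blob_effect = 2.0`,
  `activation_effect = 3.0` — chosen as at least five times every
  nuisance amplitude in the generator (nuisance activations 0.6,
  coarse noise 0.2, own-ROI selection inflation ~0.3, shared blobs
  0.4) so that all three classifiers must reach LOOCV accuracy 1.0.
* **Complementary signals**: 5 + 5 subjects, `blob_effect = 0.5`,
  `activation_effect = 0.45`. Structural blobs are invisible to the
  functional arm and vice versa, mirroring the setting where fusion
  must not lose to the better single arm (combined AUC ≥ max(arms)
  − 0.02).

## Degenerate inputs and numerical choices

* Flat or sub-8 × 8 slices yield no SIFT features; empty banks score
  Csum = 0.
* Groups with one label class train constant predictors; SVM failures
  on degenerate inputs fall back to majority-label constants.
* Zero-variance features: standardization divides by 1, correlations
  count as 0.
* All-identical scores: the EER edge returns the boundary rate
  (documented in `compute_eer()`).
* Likelihood smoothing α = 1 by default; α = 0 gives the raw formula
  with ±50 caps.
* Ties: extreme-voxel ties break by voxel index; EER ties take the
  lower threshold; ε_s ties take the smallest balancing threshold.

## Known limitations

* The SIFT detector is plain R; at the full template grid a subject
  costs minutes, not seconds. The cube-wise design parallelizes
  trivially if needed.
* In-sample stacking and the all-subjects dictionary both inject mild
  optimism at small n; the nested/`train_only` options exist for
  users who want stricter protocols.
* LOOCV metrics at n ≤ 12 are high-variance; single-cohort AUCs under
  the null legitimately range from 0.1 to 0.9, which is why the null
  check averages seeds.
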