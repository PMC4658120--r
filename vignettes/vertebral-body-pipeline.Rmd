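---
title: "Random-forest localization and segmentation of vertebral bodies"
author: "vbforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-forest localization and segmentation of vertebral bodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vbforest` implements a two-stage learning pipeline for 3D spine volumes:
per-vertebra **center localization** by regression-forest voting with hidden
Markov chain regularization, followed by per-vertebra **voxel segmentation**
by fusing a Parzen-window spatial prior with a classification-forest
appearance likelihood. This vignette explains the models, their assumptions,
the tunable parameters, and the design decisions taken where the method left
room for choices.

## Coordinate and data model

A `vb_volume` is a 3D array plus voxel spacing (mm), origin (mm) and a
*slice axis* (the axis perpendicular to the acquisition slices: axis 1 for
sagittal MR, axis 3 for axial CT). Voxel `(i, j, k)` sits at
`origin + (index − 1) · spacing`; rotated/oblique geometries are rejected at
read time rather than silently mishandled, because every stage of the
pipeline reasons in this unrotated frame. All images of a study are expected
to share one spacing (use `resample_volume()`; trilinear for intensities,
nearest-neighbor for label masks — the standard choices).

## Block features (`feature_config`, `patch_feature`)

Every learning stage uses one visual feature. A patch is divided into
`k × k × k` blocks (default `k = 4`; when the patch size is not divisible by
`k` the remainder voxels go to the last blocks along each axis, a fixed
deterministic partition). Block means are computed from integral volumes of
the intensity and of its square, so the cost per feature is `k³` constant
-time box sums regardless of patch size. The mean vector is normalized to
unit L1 norm, which removes global and slowly varying intensity scale — the
reason no inter-scan intensity standardization or bias-field correction is
applied anywhere. MR features are the `k³ = 64` normalized means; CT
features append the 64 block variances to cope with the diffuse intensity
values of CT. Two decisions the description of the method leaves open:

* **Variance-half normalization (CT).** The variance sub-vector is
  L1-normalized separately from the mean sub-vector, so both halves are
  scale-invariant. (Joint normalization would let one half's magnitude
  swamp the other's.)
* **All-zero patches** return the uniform mean vector (`1/k³` each, zero
  variances) instead of dividing by zero.

A consequence worth knowing: the feature is *gradient-sensitive by design*.
Two intensity-flat patches — one deep inside a bright body, one deep in dark
background — normalize to nearly identical vectors. Real tissue texture
breaks this tie; very homogeneous synthetic data does not (see *Phantoms*).

## Localization stage

For each vertebra a regression forest learns the displacement from a
patch's center to the body's center. Internally one `ranger` forest is
grown per displacement axis and the t-th trees are paired, so each of the
`T` conceptual trees returns one 3D displacement and `N′` test patches cast
`N′ × T` votes. Defaults absent from the method description and chosen as
standard regression-forest practice: `T = 20` trees, maximum depth 12,
minimum leaf size 5, `⌊√d_f⌋` candidate features per split, bootstrap
resampling; all configurable through `forest_config()`.

**Vote aggregation.** Votes are aggregated on the voxel grid as a sum of
isotropic Gaussian kernels with constant width `h = 1.5` and unit weights.
The per-vote covariance that a fully general formulation would require is
not estimable from a single tree prediction, so the constant-kernel
simplification *is* the production path, with two backends:

* `aggregate_votes_exact()` — the direct double loop, quadratic cost; the
  numerical oracle.
* `aggregate_votes_ifgt()` — the improved fast Gauss transform: votes are
  clustered by farthest-point clustering (centers added until the covering
  radius drops below `h/2`, capped at `ifgt_clusters`), a Taylor expansion
  of total degree ≤ `ifgt_order` (default 10) is accumulated per cluster,
  and each grid voxel evaluates only clusters within an accuracy-derived
  cutoff radius. The contract — maximum relative error ≤ `ifgt_epsilon`
  (default 1e-3) at every voxel whose exact value exceeds 1e-6 of the exact
  maximum — is asserted against the exact backend in the test suite rather
  than merely bounded on paper.

Two unit conventions had to be fixed: `h` is interpreted in **voxel units
of the aggregation grid** (it is stated unitless alongside voxel-based patch
sizes, and kernel widths below the voxel size would be meaningless on the
grid), and distances inside the kernel are therefore anisotropic in mm
exactly as the grid is.

**Chain prior and decoding.** The offsets between adjacent centers,
collected over training annotations, are modeled as Gaussians
(`learn_chain_prior()`). With few annotations the sample covariance is
rank-deficient, so the *eigenvalues* are floored at `var_floor`
(default 1 mm²) — flooring only the diagonal, the literal reading, leaves
the density improper whenever the offsets happen to be collinear, which a
handful of training subjects regularly produces. Decoding maximizes
`p(c₁)·Π pᵢ,ᵢ₊₁(cᵢ₊₁|cᵢ)·pᵢ(cᵢ)` by Viterbi dynamic programming over the
top-`k_candidates` (default 50) 26-connected local maxima of each response
volume, observation scores normalized per response (making the decoded
chain invariant to positive rescaling of any single response), ties broken
toward the lower-index candidate. `k_candidates = Inf` decodes over every
voxel — exact, and used by the tests to compare against exhaustive
enumeration.

**Coarse-to-fine.** The coarse pass samples patches over the whole volume
downsampled 4× in-plane (block averaging, which anti-aliases the features;
the inter-slice axis keeps its resolution), aggregates per-vertebra
responses and decodes the chain. The fine pass re-votes at original
resolution only inside a box of half-width 30 mm around each coarse center
(the method says only "a reduced small local region"; 30 mm covers one
vertebral height with margin and is configurable), and the final center is
the argmax of the fine response. Training mirrors this: coarse forests are
trained on patches from the whole downsampled volume, fine forests on
patches within 30 mm of the true center.

## Segmentation stage

Around each detected center an ROI is defined. The method never states the
ROI size; it is learned from data as the per-axis maximum extent of the
center-aligned training masks, dilated by 25%. Inside the ROI:

* **Spatial prior** (`learn_spatial_prior()`): training masks are aligned by
  their true centers, averaged, and smoothed with an isotropic truncated
  Gaussian Parzen kernel (bandwidth 2 ROI voxels; boundary-renormalized so a
  constant field stays constant), clamped to [0, 1].
* **Appearance likelihood** (`appearance_likelihood()`): the mean of the
  per-tree foreground probabilities of a classification forest (Gini
  splits, leaves storing foreground fractions) on 8 × 8 × 8 patches,
  trained on `M` patches balanced 50/50 foreground/background.
* **Fusion and binarization**: `L = α·P_s + β·L_a` with α = 0.4, β = 0.6,
  thresholded at `L ≥ 0.5` (boundary inclusive), largest 26-connected
  component kept.

**The prefilter is a gate.** Voxels with `P_s ≤ 0.1` are hard-assigned
background and never reach the forest. The prefilter is described as a
compute-saver, but with the default weights a voxel with `P_s = 0.1` and a
unit likelihood would still fuse to `0.4·0.1 + 0.6 = 0.64 ≥ 0.5`, so the
gate is *not* a pure optimization — it changes semantics at prior-implausible
voxels. Making it an explicit gate (rather than an accident of evaluation
order) is the package's documented choice.

## Evaluation metrics

`localization_error()`, `mld_sd()` (SD uses the population divisor `N_c`,
matching the printed formula, not `N_c − 1`), `detection_rate()` (boundary
`R ≤ t` counts as success), `dice()` (two empty masks agree at 100%, a
documented convention), `surface_distances()` and `midsagittal_metrics()`.

Surfaces are represented by **boundary-voxel centers** (foreground voxels
with a background 6-neighbour inside the volume, in mm). AAD is directional
— automatic surface to ground truth — following the written definition; a
symmetric average sits behind a flag. HSD is the symmetric Hausdorff
distance (the directed variant is not stated; symmetric is the common
reading). The boundary-voxel representation was chosen over a marching-cubes
iso-surface because it is exactly reproducible by a brute-force oracle, and
it makes the 2D mid-sagittal metrics (boundary pixels of the center slice,
4-connectivity) *exactly* equal the 3D metrics on a one-slice volume. The
"mid-sagittal slice" is the slice through the rounded per-vertebra center
along the left–right axis — the description reports per-vertebra values and
never defines the term more precisely.

## Phantoms: what they emulate and what they do not

`generate_spine_phantom()` builds a chain of bright ellipsoids (default
five, radii (9, 13, 13) mm, inter-body offset (0, 30, 0) mm with SD
(1.5, 2, 1.5) mm jitter, per-body radius jitter 8%) on a 40 × 128 × 128
grid at (2, 1.25, 1.25) mm — a reduced sagittal-MR layout — with
foreground/background intensities 120/40 and additive Gaussian noise
(SD 12), plus a smooth multiplicative modulation for MR or a flat plateau
for CT. The chain shape (offsets, radii) is drawn first and then centered
in the grid, the way a field of view is positioned around the anatomy.
`generate_cohort()` re-draws the jitter per subject, giving the chain prior
and spatial prior realistic inter-subject variation. Sizes were chosen once
to mirror the reduced-MR convention at roughly half scale; the numbers in
the leave-one-out study are phantom numbers, *not* re-creations of any
clinical result.

What phantoms capture: the repetitive pattern that makes per-vertebra argmax
detection ambiguous (hence the HMM is genuinely exercised), anisotropic
voxels, inter-subject shape/offset variation, noise. What they do not:
realistic vertebra shape (processes, endplates), texture inside the body,
bias fields, pathology. One visible consequence: because flat interior
patches are ambiguous under the scale-invariant feature (above), the
classifier occasionally drops an interior voxel, which leaves Dice (~95%)
and AAD (<1 mm) intact but inflates the Hausdorff distance. On real tissue
the interior is textured and this particular ambiguity is much weaker.

## Numerical choices and degenerate inputs

* Variance of a block is clamped at 0 (floating-point guard `E[X²]−E[X]²`).
* Ties in response argmax and candidate ranking go to the lower linear
  voxel index; everything downstream is therefore deterministic.
* Every sampling or training function takes a seed, and a master seed
  derives distinct sub-seeds per vertebra/subject/stage; identical seeds
  give identical results (asserted in the tests, single-threaded forests).
* Masks that fill the whole volume have no boundary voxels; their "surface"
  falls back to all foreground voxels rather than erroring.
* Empty responses, single-class ROIs, absent labels, non-fitting patches and
  out-of-grid chains raise immediate errors in the constructor or sampler
  rather than propagating NaNs.

## Study sizes in the tests

The unit tests run the full pipeline on 3-body phantoms on 32 × 96 × 96
grids with ~1500 patches and 8 trees; the leave-one-out study in
`scripts/acceptance.R` uses the full 5-body default phantom with 10 trees,
N = N′ = 2000 training/test patches per vertebra and M = 3000 segmentation
patches — sizes at which the whole study completes in a few minutes on one
core while leaving the forests comfortably away from degeneracy. The
full-scale defaults (T = 20, N = 15000, N′ = 10000, M = 12000) remain the
package defaults for real data.

## Known limitations

* The vertebra set is fixed by the training configuration; the package does
  not identify which vertebrae are in an unknown field of view.
* No shape-model refinement or graph-cut post-processing of masks; the
  posterior threshold plus largest-component is the whole story.
* Oriented (direction-cosine) volume geometries are rejected, not handled.
* DICOM series must be converted to NIfTI or MetaImage first.
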