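# vbforest

Fully automatic **localization and segmentation of vertebral bodies (VBs)**
in 3D CT and MR volumes, with a unified random-forest regression +
classification framework.

Clinical spine analysis (diagnosis of disc degeneration, stenosis,
osteoporosis; measurement of bone mineral density) needs two prerequisites
from each scan: the **center of every vertebral body** and a **voxel-wise
binary mask** of each body. `vbforest` provides both stages for people
working with 3D T2-weighted spine MR or spine CT volumes, plus everything
needed to train, evaluate, and test the pipeline without any external data
(a synthetic spine-phantom generator with ground truth known by
construction).

## Method

**Localization (per vertebra, regression voting).** Patches sampled around a
body's center are described by a block feature: the patch is divided into
k×k×k blocks (k = 4) and the block mean intensities, computed in O(1) per
block from 3D integral images of I and I², are L1-normalized (64-d for MR;
CT appends the 64 block variances → 128-d). A regression forest learns the
map φ : ℝ^d_f → ℝ³ from patch appearance to the displacement **d** = **c**_gt −
**c**_patch. At test time N′ patches each cast one vote **y** = **c**′ + φ_t(**f**′)
per tree, and the N′·T votes are aggregated into a *response volume*

&nbsp;&nbsp;&nbsp;&nbsp;G(**y**ᵢ) = Σⱼ Wⱼ · exp(−‖**y**ᵢ − **y**ⱼ‖² / h²),&nbsp;&nbsp;h = 1.5 voxels, Wⱼ = 1,

evaluated either exactly (O(M·N′T), the oracle) or with the **improved fast
Gauss transform** (farthest-point clustering + truncated Taylor expansion,
O(M + N′T)). Because neighbouring vertebrae look alike, the per-vertebra
argmax is ambiguous: the ordered centers are decoded jointly as a hidden
Markov chain, p(c₁)·Π pᵢ,ᵢ₊₁(cᵢ₊₁|cᵢ)·pᵢ(cᵢ), whose transition densities are
Gaussians on the inter-body offsets learned from training annotations
(Viterbi dynamic programming). Detection is coarse-to-fine: first over the
whole volume downsampled 4× in-plane, then refined at full resolution in a
small box around each coarse center.

**Segmentation (per vertebra, posterior fusion).** In an ROI around each
detected center, a Parzen-window **spatial prior** P_s(v) (center-aligned,
kernel-smoothed average of training masks) gates and complements a
classification-forest **appearance likelihood** L_a(v) (average of per-tree
foreground probabilities, same block features, 8×8×8 patches; only voxels
with P_s > 0.1 are classified):

&nbsp;&nbsp;&nbsp;&nbsp;L(v) = α·P_s(v) + β·L_a(v),&nbsp;&nbsp;α = 0.4, β = 0.6.

The mask is L(v) ≥ 0.5, keeping the largest 26-connected component.

**Metrics.** Localization distance R (per-center Euclidean distance),
MLD ± SD (population divisor), detection rate P_t at accuracy t;
Dice overlap (%), average absolute surface distance (AAD) and Hausdorff
distance (HSD), in 3D and on the 2D mid-sagittal slice.

## Worked example

Train on three synthetic spine phantoms, localize and segment a fourth:

```r
library(vbforest)
cfg    <- phantom_config(n_vbs = 3, grid_dim = c(32, 96, 96))
cohort <- generate_cohort(cfg, 4, seed = 21)

params    <- localize_params("MR", n_train = 1500, n_test = 1500,
                             forest = forest_config(n_trees = 8))
localizer <- train_localizer(lapply(cohort[1:3], `[[`, "volume"),
                             lapply(cohort[1:3], `[[`, "centers"), params)
res <- localize(cohort[[4]]$volume, localizer, seed = 4)
res$centers
#> <vb_centers> 3 vertebral bodies (mm):
#>     x  y     z
#> L1 32 30 58.75
#> L2 32 60 60.00
#> L3 32 90 60.00

rep <- localization_report(list(res$centers), list(cohort[[4]]$centers))
#> MLD 1.20 mm (SD 0.84), detection rate at 4 mm: 100%

segmenter <- train_segmenter(lapply(cohort[1:3], `[[`, "volume"),
                             lapply(cohort[1:3], `[[`, "labels"),
                             lapply(cohort[1:3], `[[`, "centers"),
                             segment_params("MR", m_train = 3000,
                                            forest = forest_config(n_trees = 8)))
mask <- segment(cohort[[4]]$volume, res$centers, segmenter)
segmentation_report(mask, cohort[[4]]$labels, cohort[[4]]$centers)
#>   vb dice   aad  hsd dice2d aad2d hsd2d
#> 1 L1 95.2 0.502 7.81   97.6 0.345  1.25
#> 2 L2 95.3 0.749 8.00   95.8 2.703 11.52
#> 3 L3 95.6 0.717 6.13   92.7 2.702 10.08
```

The detected centers land within ~1 mm of the true ellipsoid centers (MLD
1.20 mm over the three bodies) and the masks overlap the ground truth at
Dice ≈ 95%, with sub-millimetre mean surface error. The larger Hausdorff
values come from occasional single-voxel interior holes — flat-interior
patches are ambiguous under a scale-invariant intensity feature (see the
methods vignette).

Real volumes are read with `read_volume()` (NIfTI `.nii/.nii.gz`, MetaImage
`.mhd`) and standardized with `resample_volume()`; a thin command-line
wrapper with `make-phantoms`, `train-localizer`, `localize`,
`train-segmenter`, `segment` and `evaluate` subcommands lives at
`inst/cli/vbforest.R`.

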