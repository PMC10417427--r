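---
title: "Coarse-to-fine segmentation of small lesions with csrseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine segmentation of small lesions with csrseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrseg)
```

## The problem

Small lesions (long diameter 5–30 mm) are easy to miss in anisotropic 3D
grayscale volumes such as abdominal MRI acquired at ~0.6 × 0.6 mm in-plane
resolution and 5 mm slice spacing. A single whole-volume segmentation
network tends to segment large lesions well while dropping small,
low-contrast ones: small structures contribute little to a voxel-wise
overlap loss and are diluted by downsampling. `csrseg` implements a
coarse-to-fine fusion strategy around that failure mode:

1. **Organ segmentation** restricts all later processing to the liver.
2. **Coarse lesion segmentation** runs a 3D network over the masked,
   normalized volume by sliding-window patch inference. Large lesions are
   reliably captured here.
3. **Detection** thresholds the coarse *probability* map (not the binary
   mask), labels connected components, and keeps candidates whose long
   diameter is strictly below a 30 mm size gate. Each candidate becomes a
   fixed 64 × 64 × 5 voxel box centered on its centroid.
4. **Fine segmentation** re-segments each box with a 2.5D network that
   sees five adjacent slices as channels and predicts the center slice.
5. **Fusion** replaces the coarse result inside each box with the fine
   result and keeps the coarse result elsewhere, intersected with the
   organ mask.

Passing the coarse *probabilities* to the detector is deliberate: a faint
lesion that the coarse argmax misses can still exceed the low detection
threshold (default 0.1) and be rescued by the fine stage.

## The CSR-UNet

Both stages use the same architecture family: a U-Net whose convolution
blocks are **CSR blocks** — dual 3×3(×3) convolutions with batch
normalization, a squeeze-and-excitation (SE) channel-attention module, and
a residual shortcut:

```
y = SE(relu(BN(conv(relu(BN(conv(x))))))) + shortcut(x)
```

The SE gate is `s = sigmoid(W2 relu(W1 mean(features)))`, a per-channel
multiplier strictly inside (0, 1); the shortcut is the identity when input
and output widths match and a 1×1 projection otherwise. The encoder halves
resolution `depth` times with 2×2(×2) max pooling while doubling channel
width from `base_channels`; the decoder mirrors it with transposed
convolutions (kernel = stride = pooling factor) and skip concatenations,
ending in a 1×1 convolution to two classes and a softmax.

Ordering choices the block description leaves open are resolved the way
SE-ResNets are usually built: BN before activation, SE after the second
convolution, residual addition after SE, no activation after the addition.
Convolutions that feed a batch-normalization layer carry no bias — BN
subtracts the per-channel batch mean, so such biases are exactly
gradient-free parameters.

Two variants exist:

* **3D** (`model_config("3D")`): single-channel volumetric input, 3×3×3
  kernels. Because typical inputs have few slices, the number of stages
  that also pool the slice axis is configurable (`z_pools`); pooling is
  dropped from the *earliest* stages first, which preserves through-plane
  resolution where anisotropy is worst.
* **2.5D** (`model_config("2.5D")`): a k-slice slab (default k = 5) enters
  as channels of a 2D network (3×3 kernels) that predicts the slab's
  center slice. Full volumes are processed slab-by-slab with edge slices
  replicated at the boundaries.

Inputs whose shape is not divisible by the pooling product are zero-padded
internally and cropped back, so the output grid always equals the input
grid.

The network engine itself (convolution via im2col + BLAS gemm with
hand-written adjoints, max-pool/transposed-conv index maps, batch-norm and
SE backward passes, Adam) is part of the package; its gradients are
verified against central finite differences in the test suite.

## Loss

Training minimizes the Focal Tversky loss. With foreground probabilities
`p` and binary targets `g`,

```
TI   = (Σ p·g + s) / (Σ p·g + α Σ p(1−g) + β Σ (1−p)g + s)
loss = (1 − TI)^γ
```

`α = β = 0.5` recovers soft Dice and `α = β = 1` soft Jaccard; the
defaults `α = 0.7, β = 0.3, γ = 0.75` penalize false positives harder and
sharpen the gradient as TI → 1, which keeps pressure on small foreground
regions late in training. The exponent is written directly as
`(1 − TI)^γ` with γ < 1 playing the focusing role. A single Focal-Tversky
term is used rather than an additive Focal + Tversky combination; the
additive reading is expressible by summing two configured losses but is
not a default. All three constants and the smoothing term are
configuration keys (`tversky_config()`).

## Preprocessing and patch machinery

* **Resampling** (`resample_inplane`): slices are resized independently
  (bilinear for images, nearest for labels — nearest can never invent
  label values); spacing is rescaled by the shape ratio. Through-plane
  resampling to isotropic voxels is intentionally out of scope: lesions
  are handled at native slice spacing.
* **Normalization** (`clip_normalize`): intensities between the 0.5 and
  99.5 percentiles (computed inside the organ mask when given) are mapped
  affinely to [0, 1], tails saturate. A degenerate percentile range (e.g.
  an empty ROI) returns zeros with a warning instead of failing.
* **Patching** (`plan_patches`/`assemble`): stride is
  `floor(patch·(1−overlap))` with the last patch per axis snapped to end
  exactly at the volume edge, so coverage is total. Overlapping
  predictions are averaged with per-patch weight maps; the default is a
  separable Gaussian (σ = patch/8, peak 1), which suppresses
  patch-boundary seams, with uniform weighting available. The overlap
  fraction (default 0.5) is a free parameter chosen to follow common
  sliding-window practice.
* **Augmentation** (`augment`): per-axis mirror flips with probability
  0.5, an in-plane rotation drawn uniformly from ±20°, and a
  multiplicative intensity jitter in (0.9, 1.1). Rotation is about the
  slice axis only — at 5 mm slices, out-of-plane rotations would mix
  grossly different resolutions. Image and label receive the identical
  spatial transform (linear vs. nearest interpolation).
* **Foreground-biased sampling** (`sample_patch_start`): training patches
  are centered on a random lesion voxel with probability `p_fg` (default
  0.5). This is the package's concrete reading of weighted sliding-window
  training — giving higher weight to regions the network must focus on —
  for which no formula is prescribed; foreground oversampling is the
  standard realization.
* **Adaptive planning** (`adaptive_plan`): a rule-based planner clamps the
  patch to the volume, derives a batch size from an activation-memory
  budget and passes the learning rate through. It encodes intent, not a
  search.

## Detection, fusion and their edge rules

The size gate is strict (`< 30 mm`) and measured on the candidate's long
diameter. Boxes always have the uniform crop size; boxes extending past
the volume are zero-padded at crop time and only the in-bounds window is
written back. Near-duplicate proposals (centers within half a crop) are
merged keeping the higher score — but ground-truth oracle boxes are never
merged, since distinct components are distinct lesions by construction. An
adapter (`read_external_boxes`) accepts boxes from an external detector as
JSON and re-snaps them to the uniform size about their centers.

Fusion uses **replacement** inside boxes by default: the fine stage can
then also *remove* coarse false positives inside a box, which a union
cannot; `fusion = "union"` is available. Whether coarse components below
the size gate should be dropped outside boxes is genuinely ambiguous, so
it is a switch (`drop_small_coarse`, off by default: outside boxes, all
coarse components are kept).

## Evaluation

`stratified_report` evaluates a set of cases lesion-wise, stratified by
long diameter into 5–10, 10–30 and >30 mm bins (lower-inclusive;
diameters under 5 mm cannot be quantified at 5 mm slices and fold into
5–10). Choices that the metric suite leaves open are resolved as follows:

* **Long diameter** is the in-plane Feret diameter — the maximum pairwise
  distance between voxel centers sharing a slice, maximized over slices —
  matching radiological long-axis measurement at coarse slice spacing. A
  3D Feret option exists (`in_plane = FALSE`).
* **Detection** uses greedy one-to-one assignment of predicted components
  to ground-truth lesions by descending voxel overlap (any overlap by
  default; `match_min_iou` can impose an IoU floor). A component bridging
  two lesions counts for the larger overlap only. Recall and F1 are
  lesion-level; voxel-level F1 would duplicate Dice exactly.
* **Lesion-wise Dice/IOU** are computed against the prediction restricted
  to the lesion's bounding box dilated by 5 voxels, with other lesions'
  voxels excluded from the window, so distant false positives and
  neighbouring lesions cannot contaminate a small lesion's score; bins
  report the lesion average.
* **Per-case voxel metrics** (Dice, IOU, volumetric similarity
  `1 − |FP−FN|/(2TP+FP+FN)`) are averaged over cases for the overall
  summary. Empty-vs-empty comparisons are defined as 1.

## The phantom generator

`generate_case` builds a synthetic case: an ellipsoidal organ (intensity
0.55) on a dark background (0.15) containing axis-aligned ellipsoidal
lesions with additive contrast (default drawn from 0.25–0.4), Gaussian
noise, and anisotropic spacing (default 1 × 1 × 5 mm on a 96 × 96 × 20
grid — the in-plane/through-plane anisotropy of 5 mm slice MRI at a
desk-scale matrix). Each lesion's long axis lies in-plane with semiaxes
(d/2, 0.7·d/2, 0.7·d/2), so its maximum physical extent equals the
specified long diameter; centers snap to voxel centers, making the
voxelized diameter accurate to one in-plane voxel diagonal. Placement is
rejection sampling inside the organ eroded by the lesion's semiaxes, with
a one-voxel exclusion margin between lesions and a 200-retry cap that
fails loudly naming the offending lesion. Cohorts draw per-case diameters
uniformly within the requested size bins and derive per-case seeds
deterministically from the cohort seed. Intensities live in [0, 1] from
the start, matching the pipeline's normalized working range.

What the phantom does *not* emulate: MRI physics (coil bias fields,
dynamic contrast-enhancement phases), texture, irregular lesion margins,
vessels and other distractor structures, or class-dependent intensity
statistics (contrast distributions per benign/malignant tag are free
parameters; the tags themselves are sampled with a slight malignant
majority). Tests passing on phantoms therefore demonstrate that the
machinery is correct and that the coarse-to-fine design behaves as
intended under controlled contrast and noise — not clinical-grade
performance on real scans.

## Training recipes and desk-scale problem sizes

The reference recipe (learning rate 0.001, batch 16, cosine-annealed
schedule, 300 epochs, five-fold cross-validation, 192 × 192 × 80 coarse
patches, 512 × 512 in-plane matrices) describes cluster-scale training.
The package keeps those values as configuration defaults where they are
cheap (learning rate, scheduler, fold count) and documents the desk-scale
sizes it actually exercises: 96 × 96 × 20 phantoms, 48 × 48 × 12
foreground-biased training patches, base width 8, depth 3 with two
slice-axis poolings, 20 epochs. Per epoch, each case contributes one
foreground-biased patch to the coarse stage and one jittered crop per
sub-gate lesion to the fine stage, one optimization step each (effective
batch 1 — `batch_size` feeds the adaptive planner only). At these sizes
the bundled experiment — 30 training phantoms, 8 held-out, coarse 3D plus
fine 2.5D — trains in minutes on one CPU and reproduces the qualitative
claims the design makes: training loss falls well below half its initial
value, fused sub-10 mm lesion recall is at least the coarse-only recall,
and every lesion above 30 mm is recovered.

```{r, eval = FALSE}
base <- phantom_config(grid_shape = c(96L, 96L, 20L), spacing_mm = c(1, 1, 5))
cohort <- generate_cohort(base, 30, seed = 101,
                          bins = c("5-10" = 2L, "10-30" = 1L, ">30" = 1L))
tc <- train_config(epochs = 20, seed = 7, p_fg = 0.7,
                   patch_size = c(48L, 48L, 12L))
coarse <- train_model("coarse", cohort,
                      model_config("3D", base_channels = 8, depth = 3,
                                   z_pools = 2), tc)
fine <- train_model("fine", cohort,
                    model_config("2.5D", base_channels = 8, depth = 3), tc)
```

Checkpoint selection in `train_stage` keeps the per-fold model with the
lowest held-out Focal Tversky loss. Fine-stage training crops are centered
on ground-truth sub-gate lesions with ±8 voxel in-plane jitter (±1 slice),
since only "detected tumors were cropped" is prescribed.

## Numerical choices and degenerate inputs

* Batch normalization with an effective batch of one patch normalizes per
  channel over the patch's voxels; running statistics (momentum 0.9) are
  used in eval mode. When a patch is internally padded, the padded voxels
  enter the batch statistics; training patch sizes are chosen divisible by
  the pooling product so this does not arise in practice.
* Softmax/loss gradients flow through the foreground channel only; the
  two-class softmax backward handles the rest.
* `clip_normalize` on a constant (or empty-mask) volume returns zeros with
  a warning — robustness on empty ROIs beats an exception mid-cohort.
* All public voxel coordinates (patch starts, boxes, lesion centers) are
  0-based with half-open ranges; R's 1-based indexing stays internal.
* Connected components use 26-connectivity throughout.
* Seeds: phantom configs, cohort generation, weight initialization,
  k-fold splits and training loops are all explicitly seeded;
  regeneration is bit-identical.

## Known limitations

* The organ ("liver") stage is implemented and trainable but the bundled
  experiments bypass it with the known organ mask — organ segmentation on
  an ellipsoid phantom is nearly trivial and would only spend runtime.
* The built-in proposal detector is intentionally simple (threshold +
  connected components + size gate). It stands in for an anchor-based
  detection network, which is out of scope; the external-boxes adapter
  preserves that architectural seam.
* 2.5D inference predicts each slice independently from its slab; no
  through-plane smoothing is applied.
* The engine is CPU-bound and single-threaded apart from BLAS; it is
  sized for method study, not clinical throughput.
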