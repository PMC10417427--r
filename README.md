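# csrseg

Coarse-to-fine detection and segmentation of **small lesions in
anisotropic 3D volumes** — the regime of abdominal MRI at ~0.6 mm
in-plane resolution and 5 mm slice spacing, where lesions of 5–30 mm long
diameter are routinely missed by a single whole-volume segmentation
network.

The package is aimed at researchers studying small-structure segmentation
strategies: it provides the full pipeline, a synthetic phantom benchmark
so everything runs end-to-end with no external data, and a lesion-wise,
size-stratified evaluation suite.

## Method

The pipeline chains five stages (all networks are **CSR-UNets**):

1. **Organ segmentation** restricts processing to the liver.
2. **Coarse lesion segmentation** — a 3D CSR-UNet over the masked volume
   (intensities clipped to the 0.5–99.5 percentiles inside the organ and
   normalized to [0, 1]) via sliding-window patch inference with
   Gaussian-weighted overlap averaging.
3. **Detection** — connected components of the coarse *probability* map
   above a low threshold (0.1), kept only if their long diameter is
   strictly below the 30 mm size gate, each becoming a fixed 64×64×5 box
   at its centroid.
4. **Fine segmentation** — a 2.5D CSR-UNet (five slices in as channels,
   center slice out) re-segments every box.
5. **Fusion** — inside boxes the fine result replaces the coarse result;
   outside, coarse components are kept; everything is intersected with
   the organ mask.

A **CSR block** is `y = SE(relu(BN(conv(relu(BN(conv(x))))))) +
shortcut(x)`: dual 3×3(×3) convolutions with batch normalization,
squeeze-and-excitation channel attention `s = σ(W₂ relu(W₁ GAP(f)))`, and
a residual shortcut (1×1 projection when widths differ). Training
minimizes the **Focal Tversky loss**

    TI   = (Σ p·g + s) / (Σ p·g + α Σ p(1−g) + β Σ (1−p)g + s)
    L    = (1 − TI)^γ,     α = 0.7, β = 0.3, γ = 0.75

with Adam and a cosine-annealed learning rate (0.001 → ~0). Evaluation
reports Dice, IOU, volumetric similarity, lesion-level F1 and recall,
overall and stratified by long diameter (5–10 / 10–30 / >30 mm, in-plane
Feret measurement).

The neural-network engine (im2col + BLAS convolutions with hand-written
adjoints, pooling/transposed-conv index maps, batch norm, SE, Adam) is
implemented in the package itself (R + Rcpp/RcppArmadillo) and its
gradients are verified against finite differences in the test suite.

## Worked example

Generate a phantom with lesions of 8, 20 and 40 mm, run the pipeline with
ground-truth oracles at every stage (the configuration used to validate
the plumbing), and evaluate:

```r
library(csrseg)
cfg <- phantom_config(grid_shape = c(96L, 96L, 20L), spacing_mm = c(1, 1, 5),
                      lesion_specs = lesion_spec(c(8, 20, 40)),
                      noise_sigma = 0.02, seed = 3)
case <- generate_case(cfg)
lesion_records(case$lesion_label)[, c("lesion_id", "n_voxels",
                                      "long_diameter_mm", "size_bin")]
#>   lesion_id n_voxels long_diameter_mm size_bin
#> 1         1       33                8     5-10
#> 2         2      429               20    10-30
#> 3         3     3277               40      >30

pred <- infer_case(case$image, list(coarse = "oracle", fine = "oracle"),
                   config = pipeline_config(detector = list(kind = "oracle",
                     threshold = 0.1, size_gate_mm = 30,
                     crop_size = c(64L, 64L, 5L), min_score = 0)),
                   liver_mask = case$liver_label, truth = case$lesion_label)
pred
#> <case_prediction 96x96x20: 2 boxes, 3739 fused foreground voxels>

stratified_report(list(list(gt = case$lesion_label, pred = pred$fused_mask)))
#> Overall (case-averaged voxel metrics, pooled lesion detection):
#>  dice iou f1 vs recall n_cases n_lesions
#>     1   1  1  1      1       1         3
#>
#> By long-diameter bin (lesion-averaged):
#>  size_bin n_lesions dice iou f1 recall
#>      5-10         1    1   1  1      1
#>     10-30         1    1   1  1      1
#>       >30         1    1   1  1      1
```

The measured long diameters recover the specified 8/20/40 mm exactly at
this spacing; only the two sub-30 mm lesions receive detection boxes (the
40 mm lesion is left to the coarse stage); and the oracle path reproduces
the ground truth perfectly — every report cell is 1.

Real training replaces the oracles:

```r
cohort <- generate_cohort(cfg, 30, seed = 101,
                          bins = c("5-10" = 2L, "10-30" = 1L, ">30" = 1L))
tc   <- train_config(epochs = 20, seed = 7, p_fg = 0.7,
                     patch_size = c(48L, 48L, 12L))
coarse <- train_model("coarse", cohort,
                      model_config("3D", base_channels = 8, depth = 3,
                                   z_pools = 2), tc)
fine   <- train_model("fine", cohort,
                      model_config("2.5D", base_channels = 8, depth = 3), tc)
pred   <- infer_case(case$image,
                     list(coarse = coarse$model, fine = fine$model),
                     config = pipeline_config(patch_size = c(64L, 64L, 20L)),
                     liver_mask = case$liver_label)
```

A command-line wrapper with `phantom`, `train`, `infer` and `evaluate`
subcommands is installed at `inst/scripts/csrseg`.

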