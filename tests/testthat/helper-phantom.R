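# shared fixtures: small phantoms and independent brute-force oracles

small_phantom <- function(seed = 1L, lesions = c(8, 20), noise = 0,
                          grid = c(64L, 64L, 12L), contrast = 0.3) {
  phantom_config(grid_shape = grid, spacing_mm = c(1, 1, 5),
                 lesion_specs = lesion_spec(lesions, contrast = contrast),
                 noise_sigma = noise, seed = seed)
}

# brute-force in-plane Feret diameter: max pairwise distance among voxel
# centers sharing a slice (independent of the convex-hull shortcut)
bf_inplane_diameter <- function(mask, spacing) {
  vox <- which(mask != 0, arr.ind = TRUE) - 1L
  best <- 0
  for (z in unique(vox[, 3])) {
    p <- vox[vox[, 3] == z, 1:2, drop = FALSE]
    p <- sweep(p, 2, spacing[1:2], "*")
    if (nrow(p) > 1L) best <- max(best, max(stats::dist(p)))
  }
  best
}

# exhaustive per-voxel confusion loop
bf_confusion <- function(pred, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] != 0 && gt[i] != 0) tp <- tp + 1L
    if (pred[i] != 0 && gt[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && gt[i] != 0) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}
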