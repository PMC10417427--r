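# Preprocessing and patch machinery: in-plane resampling, percentile
# clip-normalization, sliding-window patch planning with uniform or
# Gaussian weighting, online augmentation (flips, in-plane rotations,
# intensity scaling), and 2.5D multi-slice slab construction.

# In-plane warp core. xin/yin are (out_nx x out_ny) matrices of continuous
# 1-based input coordinates, applied identically to every slice. `extend`
# clamps coordinates to the grid (edge extension, used for resizing);
# otherwise out-of-grid samples take `fill` (used for rotation).
warp_inplane <- function(values, xin, yin, mode, extend = FALSE, fill = 0) {
  d <- dim(values)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  onx <- nrow(xin); ony <- ncol(xin)
  ok <- if (extend) TRUE else (xin >= 0.5 & xin <= nx + 0.5 &
                               yin >= 0.5 & yin <= ny + 0.5)
  if (extend) {
    xin <- pmin(pmax(xin, 1), nx)
    yin <- pmin(pmax(yin, 1), ny)
  }
  out <- array(fill, c(onx, ony, nz))
  if (mode == "nearest") {
    ix <- pmin(pmax(round(xin), 1), nx)
    iy <- pmin(pmax(round(yin), 1), ny)
    idx <- (iy - 1) * nx + ix
    for (z in seq_len(nz)) {
      sl <- values[, , z]
      o <- sl[idx]
      o[!ok] <- fill
      out[, , z] <- matrix(o, onx, ony)
    }
  } else {
    x0 <- pmin(pmax(floor(xin), 1), nx)
    y0 <- pmin(pmax(floor(yin), 1), ny)
    x1 <- pmin(x0 + 1, nx)
    y1 <- pmin(y0 + 1, ny)
    wx <- pmin(pmax(xin - x0, 0), 1)
    wy <- pmin(pmax(yin - y0, 0), 1)
    i00 <- (y0 - 1) * nx + x0; i10 <- (y0 - 1) * nx + x1
    i01 <- (y1 - 1) * nx + x0; i11 <- (y1 - 1) * nx + x1
    for (z in seq_len(nz)) {
      sl <- values[, , z]
      o <- (1 - wx) * (1 - wy) * sl[i00] + wx * (1 - wy) * sl[i10] +
        (1 - wx) * wy * sl[i01] + wx * wy * sl[i11]
      o[!ok] <- fill
      out[, , z] <- matrix(o, onx, ony)
    }
  }
  out
}

#' Resample a volume in-plane to a target matrix size
#'
#' Slices are resized independently; the slice axis is untouched. Images
#' use bilinear interpolation, label volumes must use nearest neighbour
#' (which introduces no label values absent from the input). The in-plane
#' spacing is rescaled by the shape ratio.
#'
#' @param volume a [volume_grid()] or [label_volume()].
#' @param target_xy integer(2) target in-plane shape (e.g. c(512, 512)).
#' @param mode "linear" or "nearest"; defaults to nearest for labels,
#'   linear for images.
#' @return Same type as the input.
#' @export
resample_inplane <- function(volume, target_xy,
                             mode = if (is_label_volume(volume)) "nearest"
                                    else "linear") {
  stopifnot(is_volume_grid(volume) || is_label_volume(volume))
  target_xy <- as.integer(target_xy)
  if (length(target_xy) != 2L || any(target_xy <= 0)) {
    stop("target_xy must be 2 positive integers")
  }
  mode <- match.arg(mode, c("linear", "nearest"))
  if (is_label_volume(volume) && mode == "linear") {
    stop("label volumes must be resampled with nearest-neighbour mode")
  }
  d <- dim(volume$values)
  if (all(d[1:2] == target_xy)) return(volume)
  sx <- d[1] / target_xy[1]
  sy <- d[2] / target_xy[2]
  xs <- (seq_len(target_xy[1]) - 0.5) * sx + 0.5
  ys <- (seq_len(target_xy[2]) - 0.5) * sy + 0.5
  xin <- matrix(xs, target_xy[1], target_xy[2])
  yin <- matrix(ys, target_xy[1], target_xy[2], byrow = TRUE)
  vals <- warp_inplane(volume$values, xin, yin, mode, extend = TRUE)
  spacing <- c(volume$spacing_mm[1] * sx, volume$spacing_mm[2] * sy,
               volume$spacing_mm[3])
  if (is_label_volume(volume)) {
    label_volume(array(as.integer(round(vals)), dim = dim(vals)), spacing)
  } else {
    volume_grid(vals, spacing)
  }
}

#' Percentile clip and min-max normalization
#'
#' Retains intensities between the `lo_pct` and `hi_pct` percentiles
#' (computed over `mask` voxels when given, e.g. within the liver) and maps
#' them affinely onto [0, 1]; values beyond the cuts saturate at 0/1. A
#' degenerate percentile range yields an all-zero volume with a warning.
#'
#' @param volume a [volume_grid()].
#' @param lo_pct,hi_pct percentile cuts (defaults 0.5 and 99.5).
#' @param mask optional [label_volume()]; percentiles use mask > 0 voxels.
#' @return Normalized [volume_grid()] with values in [0, 1].
#' @export
clip_normalize <- function(volume, lo_pct = 0.5, hi_pct = 99.5, mask = NULL) {
  stopifnot(is_volume_grid(volume), lo_pct < hi_pct)
  vals <- volume$values
  ref <- if (is.null(mask)) as.vector(vals) else {
    check_aligned(volume, mask)
    vals[mask$values > 0]
  }
  if (length(ref) == 0L) {
    warning("empty mask: returning an all-zero volume")
    return(volume_grid(array(0, dim(vals)), volume$spacing_mm))
  }
  q <- quantile(ref, c(lo_pct, hi_pct) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("degenerate intensity range: returning an all-zero volume")
    return(volume_grid(array(0, dim(vals)), volume$spacing_mm))
  }
  out <- (vals - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  volume_grid(out, volume$spacing_mm)
}

# separable weight map over a patch; gaussian sigma = size/8, peak 1
patch_weights <- function(size, weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  if (weighting == "uniform") return(array(1, size))
  axes <- lapply(size, function(p) {
    s <- p / 8
    w <- exp(-((seq_len(p) - (p + 1) / 2)^2) / (2 * s^2))
    w / max(w)
  })
  outer(outer(axes[[1]], axes[[2]]), axes[[3]])
}

#' Plan a sliding-window patch grid
#'
#' Stride per axis is `floor(patch * (1 - overlap_frac))`; the last patch
#' per axis is snapped so it ends exactly at the volume edge, so the union
#' of patches covers every voxel. Patch starts are 0-based.
#'
#' @param shape integer(3) volume shape.
#' @param patch integer(3) patch size; axes larger than the volume are
#'   snapped down with a warning.
#' @param overlap_frac fraction of patch overlap in [0, 1).
#' @param weighting weight map stored on each spec: "gaussian"
#'   (sigma = patch/8, peak-normalized) or "uniform".
#' @return list of `patch_spec` objects (fields `start`, `size`,
#'   `weight_map`).
#' @export
plan_patches <- function(shape, patch, overlap_frac = 0.5,
                         weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  shape <- as.integer(shape); patch <- as.integer(patch)
  stopifnot(length(shape) == 3L, length(patch) == 3L)
  if (any(patch <= 0)) stop("patch sizes must be positive")
  if (!(overlap_frac >= 0 && overlap_frac < 1)) {
    stop("overlap_frac must lie in [0, 1)")
  }
  if (any(patch > shape)) {
    warning("patch larger than volume on some axis; snapping down")
    patch <- pmin(patch, shape)
  }
  starts_axis <- function(n, p) {
    if (p >= n) return(0L)
    stride <- max(1L, as.integer(floor(p * (1 - overlap_frac))))
    s <- seq.int(0L, n - p, by = stride)
    if (s[length(s)] != n - p) s <- c(s, n - p)
    s
  }
  sx <- starts_axis(shape[1], patch[1])
  sy <- starts_axis(shape[2], patch[2])
  sz <- starts_axis(shape[3], patch[3])
  w <- patch_weights(patch, weighting)
  g <- expand.grid(x = sx, y = sy, z = sz, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    structure(list(start = c(g$x[i], g$y[i], g$z[i]), size = patch,
                   weight_map = w), class = "patch_spec")
  })
}

#' Extract the sub-volume of a patch spec
#'
#' @param volume a [volume_grid()], [label_volume()] or plain 3D array.
#' @param spec a `patch_spec` from [plan_patches()].
#' @return 3D array of the patch values.
#' @export
extract_patch <- function(volume, spec) {
  v <- if (is_volume_grid(volume) || is_label_volume(volume)) volume$values
       else volume
  s <- spec$start; p <- spec$size
  if (any(s < 0) || any(s + p > dim(v))) stop("patch spec outside volume")
  v[(s[1] + 1):(s[1] + p[1]), (s[2] + 1):(s[2] + p[2]),
    (s[3] + 1):(s[3] + p[3]), drop = FALSE]
}

#' Assemble patch outputs into a full volume
#'
#' Each voxel is the weighted average of all patch outputs covering it,
#' using each spec's weight map (or freshly computed maps when `weighting`
#' is given).
#'
#' @param patch_outputs list of lists with elements `spec` (a `patch_spec`)
#'   and `values` (array of the spec's size).
#' @param shape integer(3) output shape.
#' @param weighting optional "uniform"/"gaussian" override of the specs'
#'   stored weight maps.
#' @return 3D numeric array.
#' @export
assemble <- function(patch_outputs, shape, weighting = NULL) {
  shape <- as.integer(shape)
  num <- array(0, shape)
  den <- array(0, shape)
  for (po in patch_outputs) {
    spec <- po$spec; vals <- po$values
    if (!identical(as.integer(dim(vals)), as.integer(spec$size))) {
      stop("patch output shape does not match its spec")
    }
    if (any(spec$start + spec$size > shape)) stop("patch spec outside shape")
    w <- if (is.null(weighting)) spec$weight_map else
      patch_weights(spec$size, weighting)
    s <- spec$start; p <- spec$size
    ix <- (s[1] + 1):(s[1] + p[1]); iy <- (s[2] + 1):(s[2] + p[2])
    iz <- (s[3] + 1):(s[3] + p[3])
    num[ix, iy, iz] <- num[ix, iy, iz] + vals * w
    den[ix, iy, iz] <- den[ix, iy, iz] + w
  }
  if (any(den == 0)) stop("patch plan does not cover every voxel")
  num / den
}

#' Online augmentation parameters
#'
#' @param flip_prob_per_axis probability of mirroring each of the 3 axes.
#' @param max_rotation_deg in-plane rotation bound; the angle is drawn
#'   uniformly from [-max, +max] degrees (rotation is about the slice axis
#'   only, slices being far coarser than the in-plane grid).
#' @param intensity_scale_range multiplicative intensity jitter range.
#' @param seed optional seed for reproducible augmentation; NULL uses the
#'   ambient RNG stream.
#' @return An `augment_params` object.
#' @export
augment_params <- function(flip_prob_per_axis = 0.5, max_rotation_deg = 20,
                           intensity_scale_range = c(0.9, 1.1),
                           seed = NULL) {
  stopifnot(flip_prob_per_axis >= 0, flip_prob_per_axis <= 1,
            max_rotation_deg >= 0,
            length(intensity_scale_range) == 2L,
            all(intensity_scale_range > 0),
            intensity_scale_range[1] <= intensity_scale_range[2])
  structure(list(flip_prob_per_axis = flip_prob_per_axis,
                 max_rotation_deg = max_rotation_deg,
                 intensity_scale_range = intensity_scale_range,
                 seed = seed), class = "augment_params")
}

rotate_inplane <- function(values, angle_deg, mode) {
  d <- dim(values)
  th <- angle_deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xo <- matrix(seq_len(d[1]), d[1], d[2]) - cx
  yo <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cy
  # inverse rotation of output coords into the input grid
  xin <- cos(th) * xo + sin(th) * yo + cx
  yin <- -sin(th) * xo + cos(th) * yo + cy
  warp_inplane(values, xin, yin, mode, extend = FALSE, fill = 0)
}

#' Apply identical spatial augmentation to an image and its label
#'
#' Random per-axis mirror flips, an in-plane rotation (linear interpolation
#' for the image, nearest for the label) and a multiplicative intensity
#' scaling of the image only.
#'
#' @param image a [volume_grid()].
#' @param label an aligned [label_volume()].
#' @param params an [augment_params()].
#' @return list with elements `image` and `label`.
#' @export
augment <- function(image, label, params = augment_params()) {
  stopifnot(is_volume_grid(image), is_label_volume(label),
            inherits(params, "augment_params"))
  check_aligned(image, label)
  if (!is.null(params$seed)) set.seed(params$seed)
  iv <- image$values
  lv <- label$values
  d <- dim(iv)
  for (ax in 1:3) {
    if (runif(1) < params$flip_prob_per_axis) {
      idx <- lapply(seq_along(d), function(a)
        if (a == ax) rev(seq_len(d[a])) else seq_len(d[a]))
      iv <- do.call(`[`, c(list(iv), idx, drop = FALSE))
      lv <- do.call(`[`, c(list(lv), idx, drop = FALSE))
    }
  }
  if (params$max_rotation_deg > 0) {
    angle <- runif(1, -params$max_rotation_deg, params$max_rotation_deg)
    if (abs(angle) > 1e-9) {
      iv <- rotate_inplane(iv, angle, "linear")
      lv <- rotate_inplane(lv, angle, "nearest")
    }
  }
  if (diff(params$intensity_scale_range) > 0 ||
      params$intensity_scale_range[1] != 1) {
    iv <- iv * runif(1, params$intensity_scale_range[1],
                     params$intensity_scale_range[2])
  }
  list(image = volume_grid(iv, image$spacing_mm),
       label = label_volume(array(as.integer(round(lv)), dim = d),
                            label$spacing_mm))
}

#' Build 2.5D multi-slice slabs
#'
#' For each slice c, stacks the k surrounding slices
#' `c - (k-1)/2 ... c + (k-1)/2` as channels, replicating edge slices at
#' the volume boundaries. A 2.5D network consumes one slab and predicts its
#' center slice.
#'
#' @param volume a [volume_grid()] (or 3D array).
#' @param k odd number of slices per slab (default 5).
#' @return list with `slabs` (array nx x ny x k x nz) and `centers`
#'   (0-based center slice indices).
#' @export
make_2p5d_slabs <- function(volume, k = 5L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  v <- if (is_volume_grid(volume) || is_label_volume(volume)) volume$values
       else volume
  d <- dim(v)
  half <- (k - 1L) %/% 2L
  slabs <- array(0, c(d[1], d[2], k, d[3]))
  for (c0 in seq_len(d[3])) {
    for (j in seq_len(k)) {
      src <- min(max(c0 + j - half - 1L, 1L), d[3])
      slabs[, , j, c0] <- v[, , src]
    }
  }
  list(slabs = slabs, centers = seq_len(d[3]) - 1L)
}

#' Foreground-biased random patch start
#'
#' With probability `p_fg` (and a nonempty label) the patch is centered on
#' a random foreground voxel, otherwise placed uniformly; starts are always
#' snapped inside the volume. This realizes weighted sliding-window
#' sampling for training: regions the network must focus on (lesions) are
#' seen more often.
#'
#' @param shape integer(3) volume shape.
#' @param patch integer(3) patch size (<= shape).
#' @param label optional label array/[label_volume()] marking foreground.
#' @param p_fg probability of centering on foreground.
#' @return 0-based integer(3) patch start.
#' @export
sample_patch_start <- function(shape, patch, label = NULL, p_fg = 0.5) {
  shape <- as.integer(shape); patch <- as.integer(pmin(patch, shape))
  lv <- if (is.null(label)) NULL else
    if (is_label_volume(label)) label$values else label
  if (!is.null(lv) && any(lv > 0) && runif(1) < p_fg) {
    fg <- which(lv > 0)
    pick <- fg[ceiling(runif(1) * length(fg))]
    ctr <- arrayInd(pick, shape)[1, ] - 1L
    start <- pmin(pmax(ctr - patch %/% 2L, 0L), shape - patch)
  } else {
    start <- vapply(seq_len(3), function(a)
      as.integer(floor(runif(1) * (shape[a] - patch[a] + 1))), integer(1))
  }
  as.integer(start)
}

#' Rule-based adaptive training plan
#'
#' Chooses the effective patch size (clamped to the volume), a batch size
#' from a memory budget, and passes the learning rate through; a simple
#' stand-alone planner for desk-scale runs.
#'
#' @param volume_shape integer(3).
#' @param patch_size requested patch size (default 192 x 192 x 80).
#' @param learning_rate base learning rate (default 0.001).
#' @param memory_budget_mb activation memory budget per optimization step.
#' @param base_channels first-stage channel width used for the estimate.
#' @return list with `patch_size`, `batch_size`, `learning_rate`.
#' @export
adaptive_plan <- function(volume_shape, patch_size = c(192L, 192L, 80L),
                          learning_rate = 0.001, memory_budget_mb = 1024,
                          base_channels = 16L) {
  patch <- pmin(as.integer(patch_size), as.integer(volume_shape))
  # ~30 activation tensors of base width at full resolution dominate
  per_sample_mb <- prod(patch) * base_channels * 8 * 30 / 2^20
  batch <- max(1L, min(16L, as.integer(floor(memory_budget_mb / per_sample_mb))))
  list(patch_size = patch, batch_size = batch, learning_rate = learning_rate)
}
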