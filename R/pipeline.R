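# Pipeline orchestration: organ segmentation -> coarse lesion segmentation
# (sliding window) -> size-gated detection -> fine segmentation of fixed
# crops -> fusion, plus the training loops and cross-validation machinery.

#' Training configuration
#'
#' @param learning_rate initial learning rate (default 0.001).
#' @param batch_size nominal batch size (default 16); at desk scale each
#'   optimization step uses one sampled patch and `batch_size` informs the
#'   adaptive planner only.
#' @param epochs training epochs (reference recipe 300; desk default 20).
#' @param scheduler only "cosine" (annealed to ~0) is provided.
#' @param folds cross-validation folds (default 5).
#' @param seed training seed.
#' @param p_fg probability that a training patch is centered on foreground.
#' @param patch_size optional training patch size (defaults to the stage
#'   recipe clamped to the volume).
#' @param augment an [augment_params()] for online augmentation.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         epochs = 20L, scheduler = "cosine", folds = 5L,
                         seed = 1L, p_fg = 0.5, patch_size = NULL,
                         augment = augment_params()) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, folds >= 2,
            scheduler == "cosine")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), scheduler = scheduler,
                 folds = as.integer(folds), seed = as.integer(seed),
                 p_fg = p_fg, patch_size = patch_size, augment = augment),
            class = "train_config")
}

#' Deterministic k-fold split
#'
#' @param case_ids vector of case identifiers.
#' @param folds number of folds (>= 2, <= length(case_ids)).
#' @param seed shuffle seed.
#' @return list of `folds` lists with elements `train` and `val`; the
#'   validation sets are disjoint and cover all ids.
#' @export
kfold_split <- function(case_ids, folds, seed = 1L) {
  n <- length(case_ids)
  folds <- as.integer(folds)
  if (folds > n) stop("more folds than cases")
  if (folds < 2L) stop("folds must be >= 2")
  set.seed(as.integer(seed))
  perm <- sample(case_ids)
  assign_fold <- rep_len(seq_len(folds), n)
  lapply(seq_len(folds), function(f) {
    val <- perm[assign_fold == f]
    list(train = setdiff(perm, val), val = val)
  })
}

# per-stage preprocessed tensors for one phantom-style case
prepare_case_tensors <- function(case) {
  liver <- case$liver_label$values > 0
  norm <- clip_normalize(case$image, mask = case$liver_label)$values
  norm[!liver] <- 0
  list(norm = norm, liver = liver, lesion = case$lesion_label$values,
       spacing = case$image$spacing_mm,
       liver_int = array(as.integer(liver), dim(norm)))
}

# one (input matrix/dims, target vector) training sample per stage
stage_recipe <- function(stage) {
  switch(stage,
    liver = list(dims = "2.5D", patch = NULL),
    coarse = list(dims = "3D", patch = c(64L, 64L, 12L)),
    fine = list(dims = "2.5D", patch = DEFAULT_CROP),
    stop("unknown stage: ", stage))
}

default_model_config <- function(stage, base_channels = 8L) {
  if (stage == "coarse") {
    model_config("3D", base_channels = base_channels, depth = 3L,
                 se_reduction = 4L, z_pools = 2L)
  } else {
    model_config("2.5D", base_channels = base_channels, depth = 3L,
                 se_reduction = 4L)
  }
}

# draw the training samples (input array + binary target) one case
# contributes to an epoch: one patch (coarse/liver), or one jittered crop
# per sub-gate lesion (fine)
draw_samples <- function(stage, tens, patch, p_fg, aug) {
  if (stage == "fine") {
    return(lapply(sample(seq_along(tens$fine_boxes)), function(bi) {
      draw_sample(stage, tens, patch, p_fg, aug, box_i = bi)
    }))
  }
  list(draw_sample(stage, tens, patch, p_fg, aug))
}

draw_sample <- function(stage, tens, patch, p_fg, aug, box_i = NULL) {
  sp <- tens$spacing
  if (stage == "coarse") {
    d <- dim(tens$norm)
    patch <- pmin(patch, d)
    st <- sample_patch_start(d, patch, tens$lesion, p_fg = p_fg)
    spec <- structure(list(start = st, size = patch), class = "patch_spec")
    img <- extract_patch(tens$norm, spec)
    lab <- extract_patch(tens$lesion, spec)
    a <- augment(volume_grid(img, sp),
                 label_volume(array(as.integer(lab > 0), dim(lab)), sp), aug)
    list(input = a$image$values, target = as.numeric(a$label$values > 0))
  } else if (stage == "liver") {
    d <- dim(tens$norm)
    z <- ceiling(runif(1) * d[3])
    half <- 2L
    idx <- pmin(pmax(z + (-half):half, 1L), d[3])
    slab <- tens$norm[, , idx, drop = FALSE]
    tgt <- tens$liver_int[, , z]
    sc <- runif(1, aug$intensity_scale_range[1], aug$intensity_scale_range[2])
    list(input = slab * sc, target = as.numeric(tgt > 0))
  } else { # fine: jittered crop around a sub-gate lesion
    boxes <- tens$fine_boxes
    b <- boxes[[box_i %||% ceiling(runif(1) * length(boxes))]]
    jit <- c(round(runif(2, -8, 8)), round(runif(1, -1, 1)))
    bj <- detection_box(b$start + as.integer(jit), b$size, 1, "oracle")
    img <- crop_roi(tens$norm, bj)$values
    lab <- crop_roi(tens$lesion, bj)$values
    sc <- runif(1, aug$intensity_scale_range[1], aug$intensity_scale_range[2])
    ctr <- (dim(lab)[3] + 1L) %/% 2L
    list(input = img * sc, target = as.numeric(lab[, , ctr] > 0))
  }
}

#' Train one model for a pipeline stage
#'
#' Trains a CSR-UNet for the given stage on a list of cases with Adam and
#' a cosine-annealed learning rate. One optimization step per sampled
#' patch: per epoch each case contributes one foreground-biased 3D patch
#' (coarse stage), one random slab (liver stage), or one jittered crop per
#' ground-truth sub-gate lesion (fine stage).
#'
#' @param stage "liver", "coarse" or "fine".
#' @param cases list of `phantom_case`-like cases.
#' @param model_cfg a [model_config()]; a stage-appropriate desk-scale
#'   default is used when NULL.
#' @param train_cfg a [train_config()].
#' @param loss_cfg a [tversky_config()].
#' @param quiet suppress per-epoch messages.
#' @return list with `model`, `loss_log` (mean loss per epoch) and
#'   `lr_log`.
#' @export
train_model <- function(stage, cases, model_cfg = NULL,
                        train_cfg = train_config(),
                        loss_cfg = tversky_config(), quiet = TRUE) {
  if (length(cases) == 0L) stop("empty training fold")
  recipe <- stage_recipe(stage)
  if (is.null(model_cfg)) default_model_config(stage) -> model_cfg
  stopifnot(model_cfg$dims == recipe$dims)
  set.seed(train_cfg$seed)
  model <- build_csr_unet(model_cfg, seed = train_cfg$seed)
  opt <- adam_init(model$params)
  tensors <- lapply(cases, prepare_case_tensors)
  if (stage == "fine") {
    tensors <- lapply(tensors, function(tn) {
      lab <- label_volume(tn$lesion, tn$spacing)
      tn$fine_boxes <- oracle_boxes(lab)
      tn
    })
    tensors <- Filter(function(tn) length(tn$fine_boxes) > 0, tensors)
    if (length(tensors) == 0L) stop("fine stage: no sub-gate lesions to train on")
  }
  patch <- train_cfg$patch_size %||% recipe$patch
  loss_log <- numeric(train_cfg$epochs)
  lr_log <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    lr <- cosine_lr(train_cfg$learning_rate, ep, train_cfg$epochs)
    lr_log[ep] <- lr
    losses <- numeric(0)
    for (ci in sample(seq_along(tensors)))
    for (sm in draw_samples(stage, tensors[[ci]], patch, train_cfg$p_fg,
                            train_cfg$augment)) {
      ad <- fm_from_input(model, sm$input)
      fw <- unet_forward(model, ad$x, ad$dims, train = TRUE)
      probs <- nn_softmax(fw$logits)
      pfg <- probs[, 2]
      losses <- c(losses, focal_tversky_loss(pfg, sm$target, loss_cfg))
      dp <- focal_tversky_grad(pfg, sm$target, loss_cfg)
      dprobs <- cbind(0, as.numeric(dp))
      dlogits <- nn_softmax_bwd(probs, dprobs)
      grads <- unet_backward(model, fw, dlogits)
      model$params <- adam_step(opt, model$params, grads, lr)
    }
    loss_log[ep] <- mean(losses)
    if (!quiet) {
      message(sprintf("[%s] epoch %d/%d lr %.5f loss %.4f", stage, ep,
                      train_cfg$epochs, lr, loss_log[ep]))
    }
  }
  list(model = model, loss_log = loss_log, lr_log = lr_log)
}

stage_val_loss <- function(stage, model, cases, loss_cfg = tversky_config()) {
  mean(vapply(cases, function(cs) {
    tens <- prepare_case_tensors(cs)
    if (stage == "coarse") {
      prob <- predict_volume_3d(model, tens$norm)
      focal_tversky_loss(prob, as.numeric(tens$lesion > 0), loss_cfg)
    } else if (stage == "liver") {
      prob <- predict_volume_2p5d(model, tens$norm)
      focal_tversky_loss(prob, as.numeric(tens$liver), loss_cfg)
    } else {
      lab <- label_volume(tens$lesion, tens$spacing)
      boxes <- oracle_boxes(lab)
      if (length(boxes) == 0L) return(NA_real_)
      mean(vapply(boxes, function(b) {
        img <- crop_roi(tens$norm, b)$values
        gt <- crop_roi(tens$lesion, b)$values
        prob <- predict_volume_2p5d(model, img)
        focal_tversky_loss(prob, as.numeric(gt > 0), loss_cfg)
      }, numeric(1)))
    }
  }, numeric(1)), na.rm = TRUE)
}

#' Cross-validated training of one pipeline stage
#'
#' Splits the cohort with [kfold_split()], trains one model per fold with
#' [train_model()] and scores each on its held-out cases with the Focal
#' Tversky loss.
#'
#' @inheritParams train_model
#' @param cohort list of cases.
#' @return list with `folds` (per-fold model, loss log and validation
#'   loss), `splits` and `best_fold` (lowest validation loss).
#' @export
train_stage <- function(stage, cohort, model_cfg = NULL,
                        train_cfg = train_config(),
                        loss_cfg = tversky_config(), quiet = TRUE) {
  if (length(cohort) == 0L) stop("empty cohort")
  splits <- kfold_split(seq_along(cohort), train_cfg$folds, train_cfg$seed)
  folds <- lapply(seq_along(splits), function(f) {
    sp <- splits[[f]]
    if (length(sp$train) == 0L) stop("empty fold")
    fit <- train_model(stage, cohort[sp$train], model_cfg, train_cfg,
                       loss_cfg, quiet = quiet)
    fit$val_loss <- stage_val_loss(stage, fit$model, cohort[sp$val], loss_cfg)
    fit
  })
  vals <- vapply(folds, `[[`, numeric(1), "val_loss")
  list(folds = folds, splits = splits, best_fold = which.min(vals))
}

# full-volume 3D probability by direct forward (volume must fit in memory)
predict_volume_3d <- function(model, arr) {
  unet_apply(model, arr)$prob
}

# slice-by-slice 2.5D probability over a full volume or crop
predict_volume_2p5d <- function(model, arr) {
  sl <- make_2p5d_slabs(arr, model$config$in_channels)
  d <- dim(arr)
  out <- array(0, d)
  for (c0 in seq_len(d[3])) {
    out[, , c0] <- unet_apply(model, sl$slabs[, , , c0])$prob
  }
  out
}

# sliding-window coarse probability map
sliding_window_prob <- function(model, arr, patch, overlap_frac = 0.5,
                                weighting = "gaussian") {
  d <- dim(arr)
  patch <- pmin(as.integer(patch), d)
  specs <- plan_patches(d, patch, overlap_frac, weighting)
  outs <- lapply(specs, function(sp) {
    list(spec = sp, values = array(unet_apply(model, extract_patch(arr, sp))$prob,
                                   sp$size))
  })
  assemble(outs, d)
}

#' Pipeline inference configuration
#'
#' @param patch_size coarse-stage sliding-window patch (clamped to the
#'   volume; reference recipe 192 x 192 x 80).
#' @param overlap_frac,weighting sliding-window settings.
#' @param mask_threshold probability cut for binarizing stage outputs.
#' @param detector list: `kind` ("proposal", "oracle", "external"),
#'   `threshold`, `size_gate_mm`, `crop_size`, `min_score`, and
#'   `boxes_path` for the external adapter.
#' @param fusion "replace" (fine result replaces coarse inside each box,
#'   so fine can also remove coarse false positives) or "union".
#' @param drop_small_coarse drop coarse components below the size gate
#'   outside detection boxes (off by default).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(patch_size = c(192L, 192L, 80L),
                            overlap_frac = 0.5, weighting = "gaussian",
                            mask_threshold = 0.5,
                            detector = list(kind = "proposal",
                                            threshold = 0.1,
                                            size_gate_mm = 30,
                                            crop_size = DEFAULT_CROP,
                                            min_score = 0,
                                            boxes_path = NULL),
                            fusion = c("replace", "union"),
                            drop_small_coarse = FALSE) {
  fusion <- match.arg(fusion)
  structure(list(patch_size = as.integer(patch_size),
                 overlap_frac = overlap_frac, weighting = weighting,
                 mask_threshold = mask_threshold, detector = detector,
                 fusion = fusion, drop_small_coarse = drop_small_coarse),
            class = "pipeline_config")
}

#' Fuse coarse and fine segmentations
#'
#' Inside the union of detection boxes the fine results replace (or are
#' unioned with) the coarse result; outside, coarse components are kept.
#' The result is intersected with the liver mask.
#'
#' @param coarse_mask binary 3D array (or [label_volume()]).
#' @param fine_masks list of binary arrays of the boxes' crop size.
#' @param boxes list of `detection_box` aligned with `fine_masks`.
#' @param liver_mask binary array or [label_volume()].
#' @param rule "replace" or "union".
#' @return Binary integer 3D array.
#' @export
fuse <- function(coarse_mask, fine_masks, boxes, liver_mask,
                 rule = c("replace", "union")) {
  rule <- match.arg(rule)
  cm <- if (is_label_volume(coarse_mask)) coarse_mask$values else coarse_mask
  lm <- if (is_label_volume(liver_mask)) liver_mask$values else liver_mask
  if (!identical(dim(cm), dim(lm))) stop("grids are not aligned")
  fused <- cm != 0
  if (length(boxes)) {
    stopifnot(length(fine_masks) == length(boxes))
    for (i in seq_along(boxes)) {
      b <- boxes[[i]]
      if (any(b$start + b$size <= 0) || any(b$start >= dim(cm))) {
        stop("detection box lies outside the grid")
      }
      pl <- crop_roi(fused, b, pad_value = 0)$placement
      fn <- fine_masks[[i]] != 0
      sub <- fn[pl$dst_lo[1]:pl$dst_hi[1], pl$dst_lo[2]:pl$dst_hi[2],
                pl$dst_lo[3]:pl$dst_hi[3], drop = FALSE]
      win <- fused[pl$src_lo[1]:pl$src_hi[1], pl$src_lo[2]:pl$src_hi[2],
                   pl$src_lo[3]:pl$src_hi[3], drop = FALSE]
      new <- if (rule == "replace") sub else (win | sub)
      fused[pl$src_lo[1]:pl$src_hi[1], pl$src_lo[2]:pl$src_hi[2],
            pl$src_lo[3]:pl$src_hi[3]] <- new
    }
  }
  array(as.integer(fused & (lm != 0)), dim(cm))
}

#' Run coarse-to-fine inference on one case
#'
#' Liver mask (predicted or provided) -> intensity normalization within
#' the liver -> coarse probability by sliding-window assembly -> detection
#' boxes -> fine segmentation of each crop (slice-by-slice 2.5D) ->
#' fusion. Stage networks may be replaced by the string `"oracle"`
#' together with `truth` (the ground-truth lesion label) for oracle-path
#' validation.
#'
#' @param image a [volume_grid()].
#' @param checkpoints list with elements `liver`, `coarse`, `fine`: each a
#'   `csr_unet` (or `"oracle"` for coarse/fine; `liver` may be omitted
#'   when `liver_mask` is provided).
#' @param config a [pipeline_config()].
#' @param liver_mask optional [label_volume()] bypassing the liver stage.
#' @param truth optional ground-truth lesion [label_volume()], required by
#'   oracle stages and the oracle detector.
#' @return A `case_prediction`: `liver_mask`, `coarse_prob`,
#'   `coarse_mask`, `boxes`, `fine_masks`, `fused_mask`.
#' @export
infer_case <- function(image, checkpoints, config = pipeline_config(),
                       liver_mask = NULL, truth = NULL) {
  stopifnot(is_volume_grid(image))
  d <- dim(image$values)
  sp <- image$spacing_mm

  if (is.null(liver_mask)) {
    if (is.null(checkpoints$liver)) stop("missing checkpoint for stage 'liver'")
    lp <- predict_volume_2p5d(checkpoints$liver, image$values)
    liver_mask <- label_volume(array(as.integer(lp >= config$mask_threshold), d), sp)
  }
  lv <- liver_mask$values > 0

  if (!any(lv)) {
    empty <- array(0L, d)
    return(structure(list(liver_mask = liver_mask,
                          coarse_prob = volume_grid(array(0, d), sp),
                          coarse_mask = empty, boxes = list(),
                          fine_masks = list(),
                          fused_mask = label_volume(empty, sp)),
                     class = "case_prediction"))
  }

  norm <- clip_normalize(image, mask = liver_mask)$values
  norm[!lv] <- 0

  if (identical(checkpoints$coarse, "oracle")) {
    if (is.null(truth)) stop("oracle coarse stage requires `truth`")
    prob <- array(as.numeric(truth$values > 0), d)
  } else if (inherits(checkpoints$coarse, "csr_unet")) {
    prob <- sliding_window_prob(checkpoints$coarse, norm, config$patch_size,
                                config$overlap_frac, config$weighting)
  } else {
    stop("missing checkpoint for stage 'coarse'")
  }
  prob[!lv] <- 0
  coarse_prob <- volume_grid(prob, sp)
  coarse_mask <- array(as.integer(prob >= config$mask_threshold), d)

  det <- config$detector
  boxes <- switch(det$kind,
    proposal = propose_boxes(coarse_prob, liver_mask, det$threshold,
                             det$size_gate_mm, det$crop_size),
    oracle = {
      if (is.null(truth)) stop("oracle detector requires `truth`")
      oracle_boxes(truth, det$size_gate_mm, det$crop_size)
    },
    external = read_external_boxes(det$boxes_path, det$crop_size,
                                   det$min_score %||% 0),
    stop("unknown detector kind: ", det$kind))

  fine_masks <- lapply(boxes, function(b) {
    if (identical(checkpoints$fine, "oracle")) {
      if (is.null(truth)) stop("oracle fine stage requires `truth`")
      array(as.integer(crop_roi(truth$values, b)$values > 0), b$size)
    } else if (inherits(checkpoints$fine, "csr_unet")) {
      img <- crop_roi(norm, b)$values
      fp <- predict_volume_2p5d(checkpoints$fine, img)
      array(as.integer(fp >= config$mask_threshold), b$size)
    } else {
      stop("missing checkpoint for stage 'fine'")
    }
  })

  cm <- coarse_mask
  if (config$drop_small_coarse) {
    comp <- label_components(cm)
    for (id in setdiff(unique(as.vector(comp)), 0L)) {
      vox <- which(comp == id, arr.ind = TRUE) - 1L
      if (long_diameter(vox, sp) < det$size_gate_mm) cm[comp == id] <- 0L
    }
  }
  fused <- fuse(cm, fine_masks, boxes, liver_mask$values, config$fusion)

  structure(list(liver_mask = liver_mask, coarse_prob = coarse_prob,
                 coarse_mask = coarse_mask, boxes = boxes,
                 fine_masks = fine_masks,
                 fused_mask = label_volume(fused, sp)),
            class = "case_prediction")
}

#' @export
print.case_prediction <- function(x, ...) {
  cat(sprintf("<case_prediction %s: %d boxes, %d fused foreground voxels>\n",
              paste(dim(x$fused_mask$values), collapse = "x"),
              length(x$boxes), sum(x$fused_mask$values)))
  invisible(x)
}

#' Write per-case prediction volumes and boxes
#'
#' Emits `liver.nii.gz`, `coarse.nii.gz`, `fused.nii.gz` and `boxes.json`.
#'
#' @param pred a `case_prediction`.
#' @param directory output directory.
#' @return file paths, invisibly.
#' @export
write_prediction <- function(pred, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sp <- pred$fused_mask$spacing_mm
  p <- c(liver = file.path(directory, "liver.nii.gz"),
         coarse = file.path(directory, "coarse.nii.gz"),
         fused = file.path(directory, "fused.nii.gz"),
         boxes = file.path(directory, "boxes.json"))
  write_volume(pred$liver_mask, p[["liver"]])
  write_volume(label_volume(pred$coarse_mask, sp), p[["coarse"]])
  write_volume(pred$fused_mask, p[["fused"]])
  write_boxes(pred$boxes, p[["boxes"]])
  invisible(p)
}
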