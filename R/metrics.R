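# Voxel-level and lesion-level evaluation, stratified by lesion long
# diameter. The long diameter is measured in-plane (per-slice Feret
# diameter, maximized over slices), matching radiological long-axis
# measurement at coarse slice spacing; a full 3D Feret option exists.

SIZE_BINS <- c("5-10", "10-30", ">30")

as_binary <- function(x) {
  v <- if (is_label_volume(x) || is_volume_grid(x)) x$values else x
  v != 0
}

#' Voxel confusion counts between a binary prediction and ground truth
#'
#' @param pred,gt binary [label_volume()]s (any nonzero voxel is
#'   foreground) or plain arrays of identical shape.
#' @return list with integer counts `tp`, `fp`, `fn`.
#' @export
confusion <- function(pred, gt) {
  p <- as_binary(pred)
  g <- as_binary(gt)
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and gt")
  tp <- sum(p & g)
  list(tp = tp, fp = sum(p) - tp, fn = sum(g) - tp)
}

#' Overlap metrics from confusion counts
#'
#' `dice = 2tp/(2tp+fp+fn)`, `iou = tp/(tp+fp+fn)`,
#' `vs = 1 - |fp-fn|/(2tp+fp+fn)` (volumetric similarity). When both masks
#' are empty (`2tp+fp+fn == 0`) all three are defined as 1.
#'
#' @param c list with elements `tp`, `fp`, `fn` (see [confusion()]).
#' @return numeric in [0, 1].
#' @export
dice <- function(c) {
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) return(1)
  2 * c$tp / d
}

#' @rdname dice
#' @export
iou <- function(c) {
  d <- c$tp + c$fp + c$fn
  if (d == 0) return(1)
  c$tp / d
}

#' @rdname dice
#' @export
vs <- function(c) {
  d <- 2 * c$tp + c$fp + c$fn
  if (d == 0) return(1)
  1 - abs(c$fp - c$fn) / d
}

#' Long diameter of a lesion component in mm
#'
#' Maximum pairwise Euclidean distance between voxel centers in physical
#' coordinates. By default the measurement is in-plane: only same-slice
#' pairs are considered and the maximum is taken over slices. A single
#' voxel has diameter 0.
#'
#' @param voxels integer matrix (n x 3) of 0-based voxel indices, or a
#'   logical/binary array.
#' @param spacing_mm numeric(3) voxel spacing.
#' @param in_plane logical; if FALSE, measure the full 3D Feret diameter.
#' @return diameter in mm.
#' @export
long_diameter <- function(voxels, spacing_mm, in_plane = TRUE) {
  if (is.array(voxels) && !is.matrix(voxels)) {
    voxels <- which(voxels != 0, arr.ind = TRUE) - 1L
  }
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (nrow(voxels) == 0L) stop("empty component has no long diameter")
  if (nrow(voxels) == 1L) return(0)
  pts <- sweep(voxels, 2, spacing_mm, "*")
  max_d2 <- function(p) {
    if (nrow(p) == 1L) return(0)
    if (nrow(p) > 8L) {
      h <- chull(p[, 1], p[, 2])
      if (length(h) >= 2L) p <- p[h, , drop = FALSE]
    }
    max(stats::dist(p))^2
  }
  if (in_plane) {
    best <- 0
    for (z in unique(voxels[, 3])) {
      p <- pts[voxels[, 3] == z, 1:2, drop = FALSE]
      best <- max(best, max_d2(p))
    }
    sqrt(best)
  } else {
    max(stats::dist(pts))
  }
}

#' Assign a long diameter to a size bin
#'
#' Bins are lower-inclusive / upper-exclusive: [0,10) is "5-10" (diameters
#' under 5 mm cannot be quantified at 5 mm slice thickness and are folded
#' into the smallest bin), [10,30) is "10-30", and 30 mm and above is ">30".
#'
#' @param diameter_mm non-negative diameter in mm (vectorized).
#' @return character vector of bins among `"5-10"`, `"10-30"`, `">30"`.
#' @export
size_bin <- function(diameter_mm) {
  if (any(diameter_mm < 0)) stop("diameter must be non-negative")
  ifelse(diameter_mm < 10, "5-10", ifelse(diameter_mm < 30, "10-30", ">30"))
}

#' Label connected components (26-connectivity)
#'
#' @param mask binary array or [label_volume()].
#' @return integer array of component labels, 0 = background.
#' @export
label_components <- function(mask) {
  v <- if (is_label_volume(mask) || is_volume_grid(mask)) mask$values else mask
  d <- dim(v)
  lab <- cs_label_components(as.integer(v != 0), as.integer(d))
  array(lab, dim = d)
}

#' Extract per-lesion records from a lesion label volume
#'
#' @param label a [label_volume()] (distinct positive integers per lesion,
#'   or any labeling; components are re-derived at 26-connectivity).
#' @param in_plane passed to [long_diameter()].
#' @return data.frame with lesion_id, n_voxels, long_diameter_mm, size_bin,
#'   and a list-column `voxels` of 0-based index matrices.
#' @export
lesion_records <- function(label, in_plane = TRUE) {
  stopifnot(is_label_volume(label))
  comp <- label_components(label$values)
  ids <- setdiff(sort(unique(as.vector(comp))), 0L)
  recs <- lapply(ids, function(id) {
    vox <- which(comp == id, arr.ind = TRUE) - 1L
    d <- long_diameter(vox, label$spacing_mm, in_plane = in_plane)
    list(lesion_id = id, n_voxels = nrow(vox), long_diameter_mm = d,
         size_bin = size_bin(d), voxels = vox)
  })
  df <- data.frame(
    lesion_id = vapply(recs, `[[`, integer(1), "lesion_id"),
    n_voxels = vapply(recs, `[[`, integer(1), "n_voxels"),
    long_diameter_mm = vapply(recs, `[[`, numeric(1), "long_diameter_mm"),
    size_bin = vapply(recs, `[[`, character(1), "size_bin"),
    stringsAsFactors = FALSE)
  df$voxels <- lapply(recs, `[[`, "voxels")
  df
}

#' Match ground-truth lesions to predicted components
#'
#' Predicted components are assigned one-to-one to ground-truth lesions by
#' greedy descending voxel overlap; a ground-truth lesion counts detected
#' when a component is assigned to it (optionally requiring a minimum IoU).
#' Unassigned predicted components are false-positive detections.
#'
#' @param gt_label ground-truth lesion [label_volume()].
#' @param pred_mask binary predicted mask ([label_volume()] or array).
#' @param match_min_iou minimum component-vs-lesion IoU for a valid match
#'   (default 0: any voxel overlap).
#' @return list with `gt` (lesion_records plus `matched`, `matched_pred`),
#'   `n_pred_components`, `n_matched`, `recall`, `precision`, `f1`.
#' @export
match_lesions <- function(gt_label, pred_mask, match_min_iou = 0) {
  gt <- lesion_records(gt_label)
  pv <- if (is_label_volume(pred_mask) || is_volume_grid(pred_mask))
    pred_mask$values else pred_mask
  if (!identical(dim(pv), dim(gt_label$values))) stop("grids are not aligned")
  pred_comp <- label_components(pv)
  np <- max(pred_comp)
  ng <- nrow(gt)
  gt$matched <- rep(FALSE, ng)
  gt$matched_pred <- rep(NA_integer_, ng)
  if (np > 0L && ng > 0L) {
    gt_map <- array(0L, dim = dim(pv))
    for (i in seq_len(ng)) {
      v <- gt$voxels[[i]]
      gt_map[cbind(v[, 1] + 1L, v[, 2] + 1L, v[, 3] + 1L)] <- i
    }
    sel <- pred_comp > 0L & gt_map > 0L
    ov <- table(factor(gt_map[sel], levels = seq_len(ng)),
                factor(pred_comp[sel], levels = seq_len(np)))
    ov <- matrix(as.numeric(ov), nrow = ng)
    gt_sizes <- gt$n_voxels
    pred_sizes <- tabulate(pred_comp[pred_comp > 0L], nbins = np)
    used_pred <- rep(FALSE, np)
    repeat {
      if (max(ov) <= 0) break
      k <- arrayInd(which.max(ov), dim(ov))
      i <- k[1]; j <- k[2]
      iou_ij <- ov[i, j] / (gt_sizes[i] + pred_sizes[j] - ov[i, j])
      if (iou_ij >= match_min_iou && iou_ij > 0) {
        gt$matched[i] <- TRUE
        gt$matched_pred[i] <- j
        used_pred[j] <- TRUE
      }
      ov[i, ] <- -1
      ov[, j] <- -1
    }
    n_fp <- sum(!used_pred)
  } else {
    n_fp <- np
  }
  n_matched <- sum(gt$matched)
  recall <- if (ng == 0L) 1 else n_matched / ng
  precision <- if (np == 0L) 1 else n_matched / np
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(gt = gt, n_pred_components = np, n_matched = n_matched,
       recall = recall, precision = precision, f1 = f1,
       pred_comp = pred_comp)
}

# lesion-wise dice/iou in a local window: lesion bbox dilated by `margin`.
# Voxels of *other* ground-truth lesions falling inside the window are
# excluded so neighbouring lesions never contaminate each other's score.
lesionwise_overlap <- function(vox, pred_arr, comp_arr, comp_id,
                               margin = 5L) {
  d <- dim(pred_arr)
  lo <- pmax(apply(vox, 2, min) + 1L - margin, 1L)
  hi <- pmin(apply(vox, 2, max) + 1L + margin, d)
  win_pred <- pred_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] != 0
  win_comp <- comp_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  win_pred[win_comp != 0L & win_comp != comp_id] <- FALSE
  win_gt <- array(FALSE, dim = dim(win_pred))
  win_gt[cbind(vox[, 1] + 1L - lo[1] + 1L, vox[, 2] + 1L - lo[2] + 1L,
               vox[, 3] + 1L - lo[3] + 1L)] <- TRUE
  confusion(win_pred, win_gt)
}

#' Size-stratified lesion-wise evaluation over a set of cases
#'
#' Computes, per size bin and overall: lesion-wise Dice and IOU (each
#' ground-truth lesion scored against the prediction restricted to its
#' bounding box dilated by `window_margin` voxels, then averaged over
#' lesions), detection recall and F1 (greedy one-to-one matching, pooled
#' over cases; false-positive components are binned by their own long
#' diameter), plus a case-averaged voxel-level summary (Dice/IOU/VS and
#' pooled lesion recall/F1).
#'
#' @param cases list of lists with elements `gt` (lesion [label_volume()])
#'   and `pred` (binary mask, [label_volume()] or array); optionally
#'   `case_id`.
#' @param window_margin dilation (voxels) of the lesion-local comparison
#'   window.
#' @param match_min_iou passed to [match_lesions()].
#' @return list of class `stratified_report` with data.frames `overall`,
#'   `by_size` and `per_case`.
#' @export
stratified_report <- function(cases, window_margin = 5L, match_min_iou = 0) {
  if (length(cases) < 1L) stop("need at least one case")
  lesion_rows <- list()
  fp_bins <- character(0)
  per_case <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    gt_label <- cs$gt
    pred <- cs$pred
    pv <- if (is_label_volume(pred) || is_volume_grid(pred)) pred$values else pred
    m <- match_lesions(gt_label, pv, match_min_iou = match_min_iou)
    gt <- m$gt
    gt_comp <- label_components(gt_label$values)
    if (nrow(gt)) {
      for (i in seq_len(nrow(gt))) {
        cc <- lesionwise_overlap(gt$voxels[[i]], pv, gt_comp,
                                 gt$lesion_id[i], margin = window_margin)
        lesion_rows[[length(lesion_rows) + 1L]] <- data.frame(
          case = ci, size_bin = gt$size_bin[i],
          long_diameter_mm = gt$long_diameter_mm[i],
          dice = dice(cc), iou = iou(cc),
          matched = gt$matched[i], stringsAsFactors = FALSE)
      }
    }
    # false-positive pred components, binned by their own diameter
    if (m$n_pred_components > 0L) {
      used <- stats::na.omit(gt$matched_pred)
      for (j in setdiff(seq_len(m$n_pred_components), used)) {
        voxj <- which(m$pred_comp == j, arr.ind = TRUE) - 1L
        fp_bins <- c(fp_bins,
                     size_bin(long_diameter(voxj, gt_label$spacing_mm)))
      }
    }
    cc_case <- confusion(pv, gt_label$values)
    per_case[[ci]] <- data.frame(
      case = ci, dice = dice(cc_case), iou = iou(cc_case), vs = vs(cc_case),
      recall = m$recall, f1 = m$f1, n_lesions = nrow(gt),
      stringsAsFactors = FALSE)
  }
  lesions <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(case = integer(0), size_bin = character(0),
               long_diameter_mm = numeric(0), dice = numeric(0),
               iou = numeric(0), matched = logical(0))
  per_case <- do.call(rbind, per_case)

  bin_stats <- function(sel_lesions, sel_fp_bins) {
    n <- nrow(sel_lesions)
    n_matched <- sum(sel_lesions$matched)
    n_fp <- length(sel_fp_bins)
    recall <- if (n == 0) NA_real_ else n_matched / n
    precision <- if (n_matched + n_fp == 0) 1 else n_matched / (n_matched + n_fp)
    f1 <- if (is.na(recall)) NA_real_ else if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(n_lesions = n,
               dice = if (n) mean(sel_lesions$dice) else NA_real_,
               iou = if (n) mean(sel_lesions$iou) else NA_real_,
               f1 = f1, recall = recall, stringsAsFactors = FALSE)
  }
  by_size <- do.call(rbind, lapply(SIZE_BINS, function(b) {
    cbind(size_bin = b,
          bin_stats(lesions[lesions$size_bin == b, , drop = FALSE],
                    fp_bins[fp_bins == b]))
  }))
  overall_lesion <- bin_stats(lesions, fp_bins)
  overall <- data.frame(
    dice = mean(per_case$dice), iou = mean(per_case$iou),
    f1 = overall_lesion$f1, vs = mean(per_case$vs),
    recall = overall_lesion$recall,
    n_cases = nrow(per_case), n_lesions = nrow(lesions))
  structure(list(overall = overall, by_size = by_size, per_case = per_case,
                 lesions = lesions[, setdiff(names(lesions), "voxels")]),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("Overall (case-averaged voxel metrics, pooled lesion detection):\n")
  print(round(x$overall, 4), row.names = FALSE)
  cat("\nBy long-diameter bin (lesion-averaged):\n")
  print(cbind(x$by_size[1], round(x$by_size[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Write a stratified report to CSV/JSON files
#'
#' Emits `metrics_overall.csv` (Dice, IOU, F1-Score, VS, Recall) and
#' `metrics_by_size.csv` (per-bin Dice, IOU, F1-Score, Recall), plus a JSON
#' mirror `metrics.json`.
#'
#' @param report a `stratified_report`.
#' @param directory output directory.
#' @return file paths, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(directory, "metrics_overall.csv")
  p2 <- file.path(directory, "metrics_by_size.csv")
  p3 <- file.path(directory, "metrics.json")
  write.csv(report$overall, p1, row.names = FALSE)
  write.csv(report$by_size, p2, row.names = FALSE)
  jsonlite::write_json(list(overall = report$overall, by_size = report$by_size,
                            per_case = report$per_case),
                       p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
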