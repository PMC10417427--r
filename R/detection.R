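# Size-gated detection: fixed-size ROIs (default 64x64x5 voxels) around
# candidate lesions whose long diameter is below the size gate (strictly
# < 30 mm by default). Three sources: a proposal detector over a coarse
# foreground-probability map, a ground-truth oracle, and an adapter for
# externally supplied boxes.

DEFAULT_CROP <- c(64L, 64L, 5L)

#' Construct a detection box
#'
#' Axis-aligned ROI in global 0-based voxel coordinates, half-open
#' `[start, start + size)`. Boxes always carry the uniform crop size; parts
#' outside the volume are handled by padding at crop time.
#'
#' @param start integer(3) 0-based start voxel (may be negative for boxes
#'   near the volume edge).
#' @param size integer(3) crop size.
#' @param score detection confidence in [0, 1].
#' @param source one of "proposal", "oracle", "external".
#' @return A `detection_box`.
#' @export
detection_box <- function(start, size = DEFAULT_CROP, score = 1,
                          source = "proposal") {
  stopifnot(length(start) == 3L, length(size) == 3L, all(size > 0),
            score >= 0, score <= 1,
            source %in% c("proposal", "oracle", "external"))
  structure(list(start = as.integer(start), size = as.integer(size),
                 score = as.numeric(score), source = source),
            class = "detection_box")
}

box_from_centroid <- function(centroid, crop_size, score, source) {
  start <- as.integer(round(centroid)) - as.integer(crop_size) %/% 2L
  detection_box(start, crop_size, score, source)
}

# merge boxes whose centers fall within half a crop of each other,
# keeping the higher score
merge_duplicate_boxes <- function(boxes) {
  if (length(boxes) <= 1L) return(boxes)
  keep <- rep(TRUE, length(boxes))
  ctr <- t(vapply(boxes, function(b) b$start + b$size / 2, numeric(3)))
  half <- boxes[[1]]$size / 2
  ord <- order(-vapply(boxes, `[[`, numeric(1), "score"))
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (j in seq_along(ord)[-seq_len(i)]) {
      b <- ord[j]
      if (keep[b] && all(abs(ctr[a, ] - ctr[b, ]) < half)) keep[b] <- FALSE
    }
  }
  boxes[keep]
}

boxes_from_components <- function(comp, spacing, size_gate_mm, crop_size,
                                  scores_fun, source, merge = TRUE) {
  ids <- setdiff(sort(unique(as.vector(comp))), 0L)
  boxes <- list()
  for (id in ids) {
    vox <- which(comp == id, arr.ind = TRUE) - 1L
    d <- long_diameter(vox, spacing)
    if (d >= size_gate_mm) next   # strict gate: detect only sub-gate lesions
    boxes[[length(boxes) + 1L]] <-
      box_from_centroid(colMeans(vox), crop_size, scores_fun(comp == id), source)
  }
  if (merge) boxes <- merge_duplicate_boxes(boxes)
  boxes[order(-vapply(boxes, `[[`, numeric(1), "score"))]
}

#' Propose detection boxes from a coarse probability map
#'
#' Thresholds the foreground probability inside the liver, labels
#' connected components, keeps those with long diameter strictly below the
#' size gate, and emits a uniform-size box centered on each component
#' centroid, scored by the component's mean probability (descending).
#' Near-duplicate boxes (centers within half a crop) are merged keeping
#' the higher score.
#'
#' @param prob_map foreground probability [volume_grid()] (values in
#'   [0, 1]).
#' @param liver_mask binary [label_volume()] restricting candidates.
#' @param threshold probability threshold (default 0.1; deliberately low
#'   to favor recall of faint small lesions).
#' @param size_gate_mm size gate in mm (default 30, strict `<`).
#' @param crop_size uniform crop size (default 64 x 64 x 5).
#' @return list of `detection_box`, sorted by descending score.
#' @export
propose_boxes <- function(prob_map, liver_mask, threshold = 0.1,
                          size_gate_mm = 30, crop_size = DEFAULT_CROP) {
  stopifnot(is_volume_grid(prob_map))
  pv <- prob_map$values
  if (min(pv) < 0 || max(pv) > 1) stop("prob_map values must lie in [0, 1]")
  mask <- pv >= threshold
  if (!is.null(liver_mask)) {
    check_aligned(prob_map, liver_mask)
    mask <- mask & (liver_mask$values > 0)
  }
  comp <- label_components(mask)
  boxes_from_components(comp, prob_map$spacing_mm, size_gate_mm, crop_size,
                        scores_fun = function(sel) mean(pv[sel]),
                        source = "proposal")
}

#' Oracle detection boxes from a ground-truth lesion label
#'
#' As [propose_boxes()] but on the ground truth; every sub-gate lesion
#' yields a box with score 1, centered on its centroid.
#'
#' @param lesion_label lesion [label_volume()].
#' @param size_gate_mm size gate in mm (strict `<`).
#' @param crop_size uniform crop size.
#' @return list of `detection_box`.
#' @export
oracle_boxes <- function(lesion_label, size_gate_mm = 30,
                         crop_size = DEFAULT_CROP) {
  stopifnot(is_label_volume(lesion_label))
  comp <- label_components(lesion_label$values)
  # ground-truth components are distinct lesions: one box each, no merging
  boxes_from_components(comp, lesion_label$spacing_mm, size_gate_mm,
                        crop_size, scores_fun = function(sel) 1,
                        source = "oracle", merge = FALSE)
}

#' Crop a fixed-size ROI, padding outside the volume
#'
#' The crop has exactly the box size; out-of-bounds regions are padded
#' with `pad_value` (zero for images, background for labels). The returned
#' placement record allows exact paste-back of the in-bounds sub-window.
#'
#' @param volume a [volume_grid()], [label_volume()] or 3D array.
#' @param box a `detection_box`.
#' @param pad_value padding value (default 0).
#' @return list with `values` (array of box size) and `placement`
#'   (1-based source and destination index ranges).
#' @export
crop_roi <- function(volume, box, pad_value = 0) {
  v <- if (is_volume_grid(volume) || is_label_volume(volume)) volume$values
       else volume
  d <- dim(v)
  s <- box$start
  e <- box$start + box$size        # half-open end
  if (any(e <= 0) || any(s >= d)) stop("box lies fully outside the volume")
  src_lo <- pmax(s, 0L) + 1L
  src_hi <- pmin(e, d)
  dst_lo <- src_lo - s             # 1-based within crop
  dst_hi <- dst_lo + (src_hi - src_lo)
  crop <- array(pad_value, box$size)
  crop[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    v[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  list(values = crop,
       placement = list(src_lo = src_lo, src_hi = src_hi,
                        dst_lo = dst_lo, dst_hi = dst_hi))
}

#' Paste a cropped result back into a full-size array
#'
#' Writes only the in-bounds sub-window recorded at crop time.
#'
#' @param target 3D array to write into.
#' @param crop_values array of the crop size.
#' @param placement placement record from [crop_roi()].
#' @return The updated array.
#' @export
paste_roi <- function(target, crop_values, placement) {
  p <- placement
  target[p$src_lo[1]:p$src_hi[1], p$src_lo[2]:p$src_hi[2],
         p$src_lo[3]:p$src_hi[3]] <-
    crop_values[p$dst_lo[1]:p$dst_hi[1], p$dst_lo[2]:p$dst_hi[2],
                p$dst_lo[3]:p$dst_hi[3]]
  target
}

#' Read externally produced detection boxes from JSON
#'
#' Expects records `{start: [x, y, z], size: [x, y, z], score: s}` (0-based
#' starts). Boxes are re-snapped to the uniform crop size about their
#' centers and filtered by `min_score`.
#'
#' @param path JSON file.
#' @param crop_size uniform crop size to snap to.
#' @param min_score drop boxes scoring below this (default 0: keep all).
#' @return list of `detection_box` with source "external".
#' @export
read_external_boxes <- function(path, crop_size = DEFAULT_CROP,
                                min_score = 0) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  boxes <- list()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$start) || is.null(r$size) || is.null(r$score) ||
        length(unlist(r$start)) != 3L || length(unlist(r$size)) != 3L) {
      stop(sprintf("malformed box record at index %d", i))
    }
    s <- as.numeric(unlist(r$start))
    sz <- as.numeric(unlist(r$size))
    sc <- as.numeric(r$score)
    if (is.na(sc)) stop(sprintf("malformed box record at index %d", i))
    if (sc < min_score) next
    ctr <- s + sz / 2 - 0.5   # centroid in voxel-index units
    boxes[[length(boxes) + 1L]] <-
      box_from_centroid(ctr, crop_size, min(max(sc, 0), 1), "external")
  }
  boxes
}

#' Write detection boxes to JSON
#'
#' @param boxes list of `detection_box`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path) {
  recs <- lapply(boxes, function(b) {
    list(start = b$start, size = b$size, score = b$score, source = b$source)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read boxes written by [write_boxes()] without re-snapping
#'
#' @param path JSON path.
#' @return list of `detection_box`.
#' @export
read_boxes <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    detection_box(unlist(r$start), unlist(r$size), r$score,
                  r$source %||% "external")
  })
}
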