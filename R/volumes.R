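#' 3D scalar volume with physical voxel spacing
#'
#' The image carrier used throughout the package: a 3D numeric array in
#' (x, y, z) axis order, z being the slice axis, plus the physical voxel
#' spacing in millimetres. Voxel indices in all public structures (patch
#' plans, detection boxes) are 0-based and ranges are half-open
#' `[start, start + size)`; R's 1-based indexing is confined to internals.
#'
#' @param values 3D numeric array, axis order (x, y, z).
#' @param spacing_mm numeric(3), strictly positive voxel spacing in mm.
#' @return An object of class `volume_grid` with elements `values` and
#'   `spacing_mm`.
#' @examples
#' v <- volume_grid(array(0, c(8, 8, 4)), c(0.5938, 0.5938, 5))
#' dim(v$values)
#' @export
volume_grid <- function(values, spacing_mm) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 strictly positive finite numbers")
  }
  if (any(!is.finite(values))) stop("volume values must be finite")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "volume_grid")
}

#' Integer-labeled volume aligned with a volume_grid
#'
#' Non-negative integer labels, 0 meaning background, voxel-for-voxel
#' aligned with its paired [volume_grid()].
#'
#' @param values 3D array of non-negative integers.
#' @param spacing_mm numeric(3), voxel spacing in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(values, spacing_mm) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(values < 0) || any(values != round(values))) {
    stop("label values must be non-negative integers")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 strictly positive numbers")
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "label_volume")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, spacing %s mm, range [%.4g, %.4g]>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s, spacing %s mm, %d positive labels>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              length(setdiff(unique(as.vector(x$values)), 0L))))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")
is_label_volume <- function(x) inherits(x, "label_volume")

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("volumes are not aligned: shapes differ")
  }
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9) {
    stop("volumes are not aligned: spacings differ")
  }
  invisible(TRUE)
}

#' Write a volume to a NIfTI file
#'
#' Images are stored as float64 and labels as int32 so that read-back
#' round-trips are bit-exact; the configured spacing is written to the
#' header pixdim.
#'
#' @param vol a [volume_grid()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume_grid(vol) || is_label_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  dt <- if (is_label_volume(vol)) "int32" else "double"
  ok <- try(RNifti::writeNifti(img, path, datatype = dt), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write NIfTI file '", path, "': ", attr(ok, "condition")$message)
  }
  invisible(path)
}

#' Read a volume from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param label logical; read as a [label_volume()] instead of a
#'   [volume_grid()].
#' @return A [volume_grid()] or [label_volume()].
#' @export
read_volume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  values <- array(as.vector(img), dim = dim(img))
  if (label) {
    label_volume(values, spacing)
  } else {
    volume_grid(values, spacing)
  }
}
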