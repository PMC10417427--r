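# Synthetic phantom: an ellipsoidal organ on a dark background, containing
# axis-aligned ellipsoidal lesions of controlled in-plane long diameter.
# Emulates the statistical structure of delayed-phase liver MRI at
# anisotropic spacing (default near 0.5938 x 0.5938 x 5 mm scaled to a desk
# grid) without any MRI physics.

#' Phantom generation settings
#'
#' Describes one synthetic case: grid geometry, organ ellipsoid, intensity
#' levels in the normalized [0,1] working range, lesion specifications and
#' additive Gaussian noise. Lesions are axis-aligned ellipsoids whose long
#' axis lies in-plane (the slice spacing is typically much coarser than the
#' lesion sizes of interest), with the maximum physical extent equal to the
#' specified long diameter.
#'
#' @param grid_shape integer(3), voxels along (x, y, z).
#' @param spacing_mm numeric(3), voxel spacing in mm; default (1, 1, 5)
#'   keeps the in-plane/through-plane anisotropy of 5 mm slice imaging.
#' @param organ_semiaxes_mm numeric(3), organ ellipsoid semiaxes in mm;
#'   default 0.42 of the physical grid extent so the organ fits with margin.
#' @param organ_intensity,background_intensity intensities in (0, 1).
#' @param lesion_specs data.frame with columns `diameter_mm` (positive),
#'   `contrast` (in [-1, 1], nonzero) and `class_tag`
#'   ("benign"/"malignant"); one row per lesion.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed; identical configs generate identical cases.
#' @return An object of class `phantom_config`.
#' @examples
#' cfg <- phantom_config(lesion_specs = lesion_spec(c(8, 20, 40)))
#' case <- generate_case(cfg)
#' nrow(case$lesion_table)
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 20L),
                           spacing_mm = c(1, 1, 5),
                           organ_semiaxes_mm = NULL,
                           organ_intensity = 0.55,
                           background_intensity = 0.15,
                           lesion_specs = lesion_spec(c(8, 20)),
                           noise_sigma = 0.02,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  extent <- grid_shape * spacing_mm
  if (is.null(organ_semiaxes_mm)) organ_semiaxes_mm <- 0.42 * extent
  organ_semiaxes_mm <- as.numeric(organ_semiaxes_mm)
  stopifnot(length(organ_semiaxes_mm) == 3L, all(organ_semiaxes_mm > 0))
  if (any(2 * organ_semiaxes_mm > extent)) {
    stop("grid does not physically contain the organ ellipsoid")
  }
  if (organ_intensity <= 0 || organ_intensity >= 1 ||
      background_intensity <= 0 || background_intensity >= 1) {
    stop("intensities must lie strictly inside (0, 1)")
  }
  lesion_specs <- as.data.frame(lesion_specs)
  needed <- c("diameter_mm", "contrast", "class_tag")
  if (!all(needed %in% names(lesion_specs))) {
    stop("lesion_specs needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(lesion_specs) > 0) {
    if (any(lesion_specs$diameter_mm <= 0)) stop("lesion diameters must be positive")
    if (any(lesion_specs$diameter_mm >= 2 * min(organ_semiaxes_mm))) {
      stop("every lesion diameter must be < 2 * min(organ_semiaxes_mm)")
    }
    if (any(lesion_specs$contrast == 0)) stop("lesion contrast must be nonzero")
    if (any(abs(lesion_specs$contrast) > 1)) stop("lesion contrast must lie in [-1, 1]")
    if (!all(lesion_specs$class_tag %in% c("benign", "malignant"))) {
      stop("class_tag must be 'benign' or 'malignant'")
    }
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 organ_semiaxes_mm = organ_semiaxes_mm,
                 organ_intensity = organ_intensity,
                 background_intensity = background_intensity,
                 lesion_specs = lesion_specs,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Build a lesion specification table
#'
#' @param diameter_mm numeric vector of long diameters in mm.
#' @param contrast lesion-minus-organ intensity contrast(s), recycled.
#' @param class_tag "benign" or "malignant", recycled.
#' @return data.frame suitable for [phantom_config()]'s `lesion_specs`.
#' @export
lesion_spec <- function(diameter_mm, contrast = 0.3, class_tag = "malignant") {
  data.frame(diameter_mm = as.numeric(diameter_mm),
             contrast = rep_len(contrast, length(diameter_mm)),
             class_tag = rep_len(class_tag, length(diameter_mm)),
             stringsAsFactors = FALSE)
}

# voxel-center coordinate (mm) of 1-based index i along an axis
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# linear indices of an axis-aligned ellipsoid given 1-based center index
ellipsoid_indices <- function(grid_shape, spacing, center_idx, semiaxes) {
  ctr <- (center_idx - 0.5) * spacing
  lo <- pmax(1L, floor((ctr - semiaxes) / spacing + 0.5))
  hi <- pmin(grid_shape, ceiling((ctr + semiaxes) / spacing + 0.5))
  ix <- seq.int(lo[1], hi[1]); iy <- seq.int(lo[2], hi[2]); iz <- seq.int(lo[3], hi[3])
  dx2 <- (((ix - 0.5) * spacing[1] - ctr[1]) / semiaxes[1])^2
  dy2 <- (((iy - 0.5) * spacing[2] - ctr[2]) / semiaxes[2])^2
  dz2 <- (((iz - 0.5) * spacing[3] - ctr[3]) / semiaxes[3])^2
  g <- expand.grid(x = ix, y = iy, z = iz, KEEP.OUT.ATTRS = FALSE)
  keep <- (rep(dx2, times = length(iy) * length(iz)) +
           rep(rep(dy2, each = length(ix)), times = length(iz)) +
           rep(dz2, each = length(ix) * length(iy))) <= 1 + 1e-12
  g <- g[keep, , drop = FALSE]
  (g$x - 1L) + grid_shape[1] * ((g$y - 1L) + grid_shape[2] * (g$z - 1L)) + 1L
}

# dilate a set of linear voxel indices by one voxel (26-neighbourhood)
dilate_indices <- function(idx, grid_shape) {
  n <- grid_shape
  i0 <- idx - 1L
  x <- i0 %% n[1]; y <- (i0 %/% n[1]) %% n[2]; z <- i0 %/% (n[1] * n[2])
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
    ok <- x2 >= 0 & x2 < n[1] & y2 >= 0 & y2 < n[2] & z2 >= 0 & z2 < n[3]
    out <- c(out, x2[ok] + n[1] * (y2[ok] + n[2] * z2[ok]) + 1L)
  }
  unique(out)
}

#' Generate one synthetic phantom case
#'
#' Draws lesion centers by rejection sampling inside the organ eroded by
#' each lesion's semiaxes, enforcing at least one background voxel between
#' any two lesions. The image is `background_intensity` outside the organ,
#' `organ_intensity` inside, `organ_intensity + contrast` inside each
#' lesion, plus Gaussian noise of sd `noise_sigma`, clamped to [0, 1].
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_case` with elements `image`
#'   ([volume_grid()]), `liver_label` (binary [label_volume()]),
#'   `lesion_label` ([label_volume()], one positive integer per lesion) and
#'   `lesion_table` (data.frame: lesion_id, diameter_mm, class_tag and the
#'   0-based center voxel cx, cy, cz).
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  n <- config$grid_shape
  sp <- config$spacing_mm
  ctr <- n * sp / 2
  ex <- ((voxel_centers(n[1], sp[1]) - ctr[1]) / config$organ_semiaxes_mm[1])^2
  ey <- ((voxel_centers(n[2], sp[2]) - ctr[2]) / config$organ_semiaxes_mm[2])^2
  ez <- ((voxel_centers(n[3], sp[3]) - ctr[3]) / config$organ_semiaxes_mm[3])^2
  organ <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  organ_arr <- array(organ, dim = n)

  lesion_lab <- array(0L, dim = n)
  blocked <- logical(prod(n))
  specs <- config$lesion_specs
  # place large lesions first: easier packing, order-independent labels kept
  ord <- if (nrow(specs)) order(-specs$diameter_mm) else integer(0)
  table_rows <- vector("list", nrow(specs))
  for (j in ord) {
    d <- specs$diameter_mm[j]
    long_axis <- sample(c(1L, 2L), 1L)
    semi <- numeric(3)
    semi[long_axis] <- d / 2
    semi[setdiff(1:2, long_axis)] <- 0.7 * d / 2
    semi[3] <- 0.7 * d / 2
    shrunk <- config$organ_semiaxes_mm - semi
    if (any(shrunk <= 0)) {
      stop(sprintf("lesion %d (%.1f mm) cannot fit inside the organ", j, d))
    }
    placed <- FALSE
    for (try in seq_len(200L)) {
      cand <- ceiling(runif(3) * n) # uniform voxel index
      cc <- (cand - 0.5) * sp
      if (sum(((cc - ctr) / shrunk)^2) > 1) next
      idx <- ellipsoid_indices(n, sp, cand, semi)
      if (length(idx) == 0L || any(blocked[idx])) next
      # the erosion test above is approximate for ellipsoid-in-ellipsoid;
      # enforce voxel-exact containment in the discrete organ mask
      if (!all(organ_arr[idx])) next
      lesion_lab[idx] <- j
      blocked[dilate_indices(idx, n)] <- TRUE
      table_rows[[j]] <- data.frame(
        lesion_id = j, diameter_mm = d, class_tag = specs$class_tag[j],
        cx = cand[1] - 1L, cy = cand[2] - 1L, cz = cand[3] - 1L,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "placement failed for lesion %d (diameter %.1f mm) after 200 retries",
        j, d))
    }
  }
  lesion_table <- if (nrow(specs)) do.call(rbind, table_rows) else
    data.frame(lesion_id = integer(0), diameter_mm = numeric(0),
               class_tag = character(0), cx = integer(0), cy = integer(0),
               cz = integer(0))

  img <- array(config$background_intensity, dim = n)
  img[organ_arr] <- config$organ_intensity
  for (j in seq_len(nrow(specs))) {
    sel <- lesion_lab == j
    img[sel] <- config$organ_intensity + specs$contrast[j]
  }
  if (config$noise_sigma > 0) {
    img <- img + rnorm(length(img), 0, config$noise_sigma)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(
    image = volume_grid(img, sp),
    liver_label = label_volume(array(as.integer(organ_arr), dim = n), sp),
    lesion_label = label_volume(lesion_lab, sp),
    lesion_table = lesion_table,
    config = config), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s, %d lesions (%s mm)>\n",
              paste(dim(x$image$values), collapse = "x"),
              nrow(x$lesion_table),
              paste(signif(x$lesion_table$diameter_mm, 3), collapse = ", ")))
  invisible(x)
}

#' Generate a cohort of independent phantom cases
#'
#' Per-case seeds are derived deterministically from `seed`. If `bins` is
#' given, each case draws its lesion long diameters uniformly within each
#' size bin ("5-10", "10-30", ">30" mm, the >30 bin spanning 30.5-40 mm),
#' with contrast magnitudes drawn from `contrast_range` and class tags
#' sampled with a slight malignant majority; otherwise the `config` lesion
#' specs are reused for every case.
#'
#' @param config base [phantom_config()].
#' @param n_cases number of cases, >= 1.
#' @param seed cohort seed.
#' @param bins optional named integer vector of per-case lesion counts,
#'   names among `"5-10"`, `"10-30"`, `">30"`.
#' @param contrast_range range of positive lesion contrasts when drawing
#'   from bins.
#' @param p_malignant probability a drawn lesion is tagged malignant.
#' @return list of `phantom_case` objects.
#' @export
generate_cohort <- function(config, n_cases, seed = config$seed, bins = NULL,
                            contrast_range = c(0.25, 0.4),
                            p_malignant = 0.55) {
  stopifnot(inherits(config, "phantom_config"))
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) stop("n_cases must be >= 1")
  set.seed(as.integer(seed))
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  ranges <- list("5-10" = c(5, 10), "10-30" = c(10, 30), ">30" = c(30.5, 40))
  specs_list <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    if (is.null(bins)) {
      specs_list[[i]] <- config$lesion_specs
    } else {
      if (!all(names(bins) %in% names(ranges))) {
        stop("bin names must be among: ", paste(names(ranges), collapse = ", "))
      }
      ds <- unlist(lapply(names(bins), function(b) {
        runif(bins[[b]], ranges[[b]][1], ranges[[b]][2])
      }))
      specs_list[[i]] <- data.frame(
        diameter_mm = as.numeric(ds),
        contrast = runif(length(ds), contrast_range[1], contrast_range[2]),
        class_tag = ifelse(runif(length(ds)) < p_malignant,
                           "malignant", "benign"),
        stringsAsFactors = FALSE)
    }
  }
  lapply(seq_len(n_cases), function(i) {
    cfg <- config
    cfg$lesion_specs <- specs_list[[i]]
    cfg$seed <- case_seeds[i]
    generate_case(cfg)
  })
}

#' Write a phantom case to disk
#'
#' Writes `image.nii.gz`, `liver.nii.gz` and `lesion.nii.gz` (spacing in the
#' NIfTI header) plus a `lesions.csv` sidecar.
#'
#' @param case a `phantom_case`.
#' @param directory output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_case <- function(case, directory) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory '", directory, "'")
  paths <- c(image = file.path(directory, "image.nii.gz"),
             liver = file.path(directory, "liver.nii.gz"),
             lesion = file.path(directory, "lesion.nii.gz"),
             table = file.path(directory, "lesions.csv"))
  write_volume(case$image, paths[["image"]])
  write_volume(case$liver_label, paths[["liver"]])
  write_volume(case$lesion_label, paths[["lesion"]])
  write.csv(case$lesion_table, paths[["table"]], row.names = FALSE)
  invisible(paths)
}

#' Read back a phantom case written by [write_case()]
#'
#' @param directory case directory.
#' @return A `phantom_case` (without the generating config).
#' @export
read_case <- function(directory) {
  image <- read_volume(file.path(directory, "image.nii.gz"))
  liver <- read_volume(file.path(directory, "liver.nii.gz"), label = TRUE)
  lesion <- read_volume(file.path(directory, "lesion.nii.gz"), label = TRUE)
  tab <- read.csv(file.path(directory, "lesions.csv"),
                  stringsAsFactors = FALSE)
  structure(list(image = image, liver_label = liver, lesion_label = lesion,
                 lesion_table = tab, config = NULL), class = "phantom_case")
}

#' Write a cohort with a manifest
#'
#' Writes each case under `case_###/` and a `manifest.json` listing the
#' case directories.
#'
#' @param cases list of `phantom_case` objects.
#' @param directory cohort root directory.
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cases, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  dirs <- sprintf("case_%03d", seq_along(cases))
  for (i in seq_along(cases)) {
    write_case(cases[[i]], file.path(directory, dirs[i]))
  }
  manifest <- list(
    n_cases = length(cases),
    cases = dirs,
    seeds = vapply(cases, function(cs) {
      if (is.null(cs$config)) NA_integer_ else cs$config$seed
    }, integer(1)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(directory, "manifest.json"))
}
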