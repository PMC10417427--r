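test_that("generated cases honor lesion count, intensity and containment", {
  cfg <- small_phantom(seed = 3, lesions = c(8, 20, 30), noise = 0,
                       grid = c(96L, 96L, 20L))
  cs <- generate_case(cfg)
  comp <- label_components(cs$lesion_label$values)
  expect_equal(max(comp), 3L)
  expect_equal(nrow(cs$lesion_table), 3L)
  # every lesion voxel lies inside the organ
  expect_true(all(cs$liver_label$values[cs$lesion_label$values > 0] == 1L))
  # non-touching: dilating each lesion by one voxel meets no other lesion
  for (j in 1:3) {
    sel <- cs$lesion_label$values == j
    d <- dim(sel)
    vox <- which(sel, arr.ind = TRUE)
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      nb <- sweep(vox, 2, off, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      vals <- cs$lesion_label$values[nb[ok, , drop = FALSE]]
      expect_true(all(vals %in% c(0L, j)))
    }
  }
})

test_that("noise-free intensities follow the additive contrast model", {
  cfg <- phantom_config(grid_shape = c(64L, 64L, 12L), spacing_mm = c(1, 1, 5),
                        organ_intensity = 0.5, background_intensity = 0.1,
                        lesion_specs = lesion_spec(10, contrast = 0.3),
                        noise_sigma = 0, seed = 5)
  cs <- generate_case(cfg)
  inside <- cs$lesion_label$values > 0
  organ_only <- cs$liver_label$values > 0 & !inside
  expect_true(all(cs$image$values[inside] == 0.8))
  expect_true(all(cs$image$values[organ_only] == 0.5))
  expect_true(all(cs$image$values[cs$liver_label$values == 0] == 0.1))
})

test_that("measured long diameters match specification within a voxel diagonal", {
  cfg <- small_phantom(seed = 9, lesions = 20, grid = c(96L, 96L, 20L))
  cs <- generate_case(cfg)
  sel <- cs$lesion_label$values == 1L
  d_pkg <- long_diameter(sel, cs$image$spacing_mm)
  d_bf <- bf_inplane_diameter(sel, cs$image$spacing_mm)
  expect_equal(d_pkg, d_bf)
  expect_lt(abs(d_pkg - 20), sqrt(2) * 1 + 1e-9)
})

test_that("phantom generation is deterministic under the config seed", {
  cfg <- small_phantom(seed = 11, noise = 0.03)
  a <- generate_case(cfg)
  b <- generate_case(cfg)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$lesion_label$values, b$lesion_label$values)
  expect_identical(a$lesion_table, b$lesion_table)
})

test_that("impossible placements fail with an informative error", {
  expect_error(
    generate_case(phantom_config(grid_shape = c(24L, 24L, 8L),
                                 spacing_mm = c(1, 1, 5),
                                 organ_semiaxes_mm = c(10, 10, 15),
                                 lesion_specs = lesion_spec(19.5),
                                 seed = 1)),
    "lesion 1")
})

test_that("cohorts are deterministic and draw the configured bin counts", {
  cfg <- small_phantom(seed = 1)
  expect_error(generate_cohort(cfg, 0), "n_cases")
  bins <- c("5-10" = 2L, "10-30" = 2L)
  a <- generate_cohort(cfg, 5, seed = 42, bins = bins)
  b <- generate_cohort(cfg, 5, seed = 42, bins = bins)
  expect_identical(lapply(a, `[[`, "lesion_table"),
                   lapply(b, `[[`, "lesion_table"))
  pooled <- do.call(rbind, lapply(a, `[[`, "lesion_table"))
  expect_equal(sum(size_bin(pooled$diameter_mm) == "5-10"), 10L)
  expect_equal(sum(size_bin(pooled$diameter_mm) == "10-30"), 10L)
  # disjointness holds in every case
  for (cs in a) {
    expect_equal(max(label_components(cs$lesion_label$values)),
                 nrow(cs$lesion_table))
  }
})

test_that("case writing round-trips arrays, spacing and the lesion table", {
  cfg <- small_phantom(seed = 13, noise = 0.02)
  cs <- generate_case(cfg)
  dir <- withr::local_tempdir()
  write_case(cs, dir)
  rt <- read_case(dir)
  expect_identical(rt$image$values, cs$image$values)
  expect_identical(rt$liver_label$values, cs$liver_label$values)
  expect_identical(rt$lesion_label$values, cs$lesion_label$values)
  expect_equal(rt$image$spacing_mm, cs$image$spacing_mm)
  expect_equal(nrow(rt$lesion_table), nrow(cs$lesion_table))
  # header pixdim carries the configured spacing
  hdr <- RNifti::niftiHeader(file.path(dir, "image.nii.gz"))
  expect_equal(hdr$pixdim[2:4], cs$image$spacing_mm)
})
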