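test_that("the size gate keeps only sub-30 mm candidates", {
  cfg <- small_phantom(seed = 71, lesions = c(8, 40), grid = c(96L, 96L, 20L))
  cs <- generate_case(cfg)
  prob <- volume_grid(array(as.numeric(cs$lesion_label$values > 0),
                            dim(cs$image$values)), cs$image$spacing_mm)
  bx <- propose_boxes(prob, cs$liver_label)
  expect_length(bx, 1L)
  expect_equal(bx[[1]]$size, c(64L, 64L, 5L))
  empty <- volume_grid(array(0, dim(prob$values)), prob$spacing_mm)
  expect_length(propose_boxes(empty, cs$liver_label), 0L)
})

test_that("proposals are scored by mean probability, descending", {
  sp <- c(1, 1, 5)
  pv <- array(0, c(96, 96, 8))
  pv[10:13, 10:13, 4] <- 0.6
  pv[70:73, 70:73, 4] <- 0.9
  liver <- label_volume(array(1L, dim(pv)), sp)
  bx <- propose_boxes(volume_grid(pv, sp), liver, threshold = 0.1)
  expect_length(bx, 2L)
  expect_equal(vapply(bx, `[[`, numeric(1), "score"), c(0.9, 0.6))
  # centers sit on the component centroids
  ctr1 <- bx[[1]]$start + bx[[1]]$size %/% 2L
  expect_equal(ctr1[1:2], c(72L, 72L), tolerance = 1)
})

test_that("oracle boxes cover each sub-gate component, strict at 30 mm", {
  cfg <- small_phantom(seed = 72, lesions = c(6, 12, 25),
                       grid = c(96L, 96L, 20L))
  cs <- generate_case(cfg)
  bx <- oracle_boxes(cs$lesion_label)
  expect_length(bx, 3L)
  # exactly-30-mm component (31-voxel line at 1 mm spacing) is excluded
  lab <- array(0L, c(64, 64, 4))
  lab[10:40, 20, 2] <- 1L   # 30 mm long diameter
  lab[5:8, 50, 2] <- 2L     # 3 mm
  lv <- label_volume(lab, c(1, 1, 5))
  bx2 <- oracle_boxes(lv)
  expect_length(bx2, 1L)
  # box center equals the rounded component centroid
  vox <- which(lab == 2L, arr.ind = TRUE) - 1L
  expect_equal(bx2[[1]]$start + bx2[[1]]$size %/% 2L,
               as.integer(round(colMeans(vox))))
})

test_that("fixed-size crops pad at edges and paste back exactly", {
  set.seed(73)
  vol <- array(runif(40 * 40 * 8), c(40, 40, 8))
  corner <- detection_box(c(-10L, -10L, -1L), c(64L, 64L, 5L), 1, "oracle")
  cr <- crop_roi(vol, corner)
  expect_equal(dim(cr$values), c(64, 64, 5))
  expect_true(all(cr$values[1:10, , ] == 0))
  # interior crop-then-paste restores the region bit-exactly
  inner <- detection_box(c(4L, 6L, 1L), c(16L, 16L, 4L), 1, "oracle")
  cr2 <- crop_roi(vol, inner)
  target <- array(0, dim(vol))
  target <- paste_roi(target, cr2$values, cr2$placement)
  expect_identical(target[5:20, 7:22, 2:5], vol[5:20, 7:22, 2:5])
  expect_true(all(target[-(5:20), , ] == 0))
  # edge paste writes only the in-bounds sub-window
  pasted <- paste_roi(array(-1, dim(vol)), cr$values, cr$placement)
  expect_true(all(pasted[1:40, 1:40, 5:8] == -1 |
                  pasted[1:40, 1:40, 5:8] == vol[1:40, 1:40, 5:8]))
  expect_error(crop_roi(vol, detection_box(c(100L, 0L, 0L))), "outside")
})

test_that("external boxes validate, re-snap and round-trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "boxes.json")
  jsonlite::write_json(list(
    list(start = c(30, 40, 2), size = c(20, 20, 3), score = 0.8),
    list(start = c(0, 0, 0), size = c(10, 10, 2), score = 0.4)),
    p, auto_unbox = TRUE)
  bx <- read_external_boxes(p)
  expect_length(bx, 2L)
  expect_equal(bx[[1]]$size, c(64L, 64L, 5L))
  # snapped about the original center (39.5, 49.5, 3)
  expect_equal(bx[[1]]$start, c(40L - 32L, 50L - 32L, 3L - 2L))
  expect_length(read_external_boxes(p, min_score = 0.5), 1L)

  jsonlite::write_json(list(list(start = c(1, 2, 3), size = c(4, 4, 2))),
                       p, auto_unbox = TRUE)
  expect_error(read_external_boxes(p), "index 1")

  bl <- list(detection_box(c(1L, 2L, 3L), score = 0.5),
             detection_box(c(9L, 9L, 0L), score = 0.25, source = "oracle"))
  p2 <- file.path(dir, "rt.json")
  write_boxes(bl, p2)
  expect_equal(read_boxes(p2), bl)
})
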