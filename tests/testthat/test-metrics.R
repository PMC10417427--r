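test_that("confusion counts match an exhaustive per-voxel loop", {
  set.seed(41)
  for (i in 1:10) {
    pred <- array(as.integer(runif(216) < 0.4), c(6, 6, 6))
    gt <- array(as.integer(runif(216) < 0.4), c(6, 6, 6))
    cc <- confusion(pred, gt)
    bf <- bf_confusion(pred, gt)
    expect_identical(cc[c("tp", "fp", "fn")], bf[c("tp", "fp", "fn")])
  }
  k <- array(as.integer(runif(64) < 0.5), c(4, 4, 4))
  expect_equal(confusion(k, k), list(tp = sum(k), fp = 0L, fn = 0L))
  expect_error(confusion(array(0, c(2, 2, 2)), array(0, c(3, 2, 2))), "shape")
})

test_that("overlap metrics follow their closed forms and identities", {
  cc <- list(tp = 2, fp = 1, fn = 1)
  expect_equal(dice(cc), 4 / 6)
  expect_equal(iou(cc), 0.5)
  expect_equal(vs(cc), 1)
  # dice = 2 iou / (1 + iou) over random counts
  set.seed(42)
  for (i in 1:25) {
    c2 <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
               fn = sample(0:20, 1))
    if (2 * c2$tp + c2$fp + c2$fn == 0) next
    expect_equal(dice(c2), 2 * iou(c2) / (1 + iou(c2)), tolerance = 1e-12)
    expect_gte(dice(c2), iou(c2))
  }
  empty <- list(tp = 0, fp = 0, fn = 0)
  expect_equal(c(dice(empty), iou(empty), vs(empty)), c(1, 1, 1))
})

test_that("long diameter equals brute force and scales with spacing", {
  expect_equal(long_diameter(rbind(c(0, 0, 0), c(16, 0, 0)),
                             c(0.5938, 0.5938, 5)), 16 * 0.5938)
  expect_equal(long_diameter(matrix(c(3, 4, 2), 1), c(1, 1, 5)), 0)
  expect_error(long_diameter(matrix(numeric(0), 0, 3), c(1, 1, 1)), "empty")
  set.seed(43)
  for (i in 1:20) {
    arr <- array(0L, c(12, 12, 4))
    n <- sample(2:60, 1)
    idx <- cbind(sample(12, n, TRUE), sample(12, n, TRUE), sample(4, n, TRUE))
    arr[idx] <- 1L
    sp <- c(runif(1, 0.4, 2), runif(1, 0.4, 2), 5)
    expect_equal(long_diameter(arr, sp), bf_inplane_diameter(arr, sp),
                 tolerance = 1e-12)
  }
})

test_that("size bins are lower-inclusive with sub-5 mm folded into 5-10", {
  expect_equal(size_bin(3), "5-10")
  expect_equal(size_bin(c(5, 9.99, 10, 29.999, 30, 50)),
               c("5-10", "5-10", "10-30", "10-30", ">30", ">30"))
  expect_error(size_bin(-1), "non-negative")
})

test_that("lesion matching is greedy one-to-one on overlap", {
  sp <- c(1, 1, 5)
  gt <- array(0L, c(20, 20, 3))
  gt[2:4, 2:4, 2] <- 1L
  gt[10:12, 10:12, 2] <- 2L
  gtl <- label_volume(gt, sp)
  pred <- array(0L, c(20, 20, 3))
  pred[2:4, 2:4, 2] <- 1L
  m <- match_lesions(gtl, pred)
  expect_equal(m$recall, 0.5)
  m2 <- match_lesions(gtl, gt)
  expect_equal(c(m2$recall, m2$precision, m2$f1), c(1, 1, 1))
  # one bridging pred component spanning both lesions: assigned to the
  # larger overlap; the other lesion stays undetected one-to-one
  bridge <- array(0L, c(20, 20, 3))
  bridge[2:12, 2:12, 2] <- 1L
  m3 <- match_lesions(gtl, bridge)
  expect_equal(m3$n_matched, 1L)
  expect_equal(m3$recall, 0.5)
  expect_true(m3$gt$matched[which.max(m3$gt$n_voxels)])
})

test_that("stratified reports are exact for perfect predictions", {
  cfg <- small_phantom(seed = 51, lesions = c(8, 20, 32),
                       grid = c(96L, 96L, 20L))
  cs <- generate_case(cfg)
  rep <- stratified_report(list(list(gt = cs$lesion_label,
                                     pred = cs$lesion_label$values)))
  expect_equal(unlist(rep$overall[c("dice", "iou", "f1", "vs", "recall")]),
               c(dice = 1, iou = 1, f1 = 1, vs = 1, recall = 1))
  expect_true(all(rep$by_size$dice == 1, na.rm = TRUE))
  expect_true(all(rep$by_size$recall == 1, na.rm = TRUE))
  expect_equal(sum(rep$by_size$n_lesions), 3)
})

test_that("report rows agree with directly computed per-lesion metrics", {
  set.seed(52)
  cfg <- small_phantom(seed = 52, lesions = c(8, 20), grid = c(64L, 64L, 12L))
  cs <- generate_case(cfg)
  # imperfect prediction: erode lesion 2 by dropping a slice
  pred <- cs$lesion_label$values > 0
  vox2 <- which(cs$lesion_label$values == 2L, arr.ind = TRUE)
  drop_z <- max(vox2[, 3])
  pred[, , drop_z][cs$lesion_label$values[, , drop_z] == 2L] <- FALSE
  rep <- stratified_report(list(list(gt = cs$lesion_label, pred = pred)))
  # recompute lesion 2's dice directly in its dilated window
  sel2 <- cs$lesion_label$values == 2L
  lo <- pmax(apply(which(sel2, arr.ind = TRUE), 2, min) - 5L, 1L)
  hi <- pmin(apply(which(sel2, arr.ind = TRUE), 2, max) + 5L,
             dim(pred))
  wp <- pred[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  wg <- sel2[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  other <- (cs$lesion_label$values != 0L &
            !sel2)[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  wp[other] <- FALSE   # the report scores each lesion against its own window
  d2 <- dice(confusion(wp, wg))
  row2 <- rep$lesions[rep$lesions$long_diameter_mm > 15, ]
  expect_equal(row2$dice, d2)
  expect_equal(sum(rep$by_size$n_lesions), 2)
})

test_that("adding a true-positive voxel never decreases dice or recall", {
  set.seed(53)
  gt <- array(0L, c(10, 10, 2))
  gt[3:6, 3:6, 1] <- 1L
  pred <- array(0L, c(10, 10, 2))
  pred[3:4, 3:6, 1] <- 1L
  missing <- which(gt == 1L & pred == 0L)
  prev <- dice(confusion(pred, gt))
  for (vx in missing) {
    pred[vx] <- 1L
    cur <- dice(confusion(pred, gt))
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_equal(prev, 1)
})
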