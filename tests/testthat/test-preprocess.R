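test_that("in-plane resampling honors identity, constants and label sets", {
  v <- volume_grid(array(runif(32 * 32 * 4), c(32, 32, 4)), c(1, 1, 5))
  expect_identical(resample_inplane(v, c(32, 32))$values, v$values)

  const <- volume_grid(array(0.7, c(16, 16, 3)), c(2, 2, 5))
  up <- resample_inplane(const, c(32, 32), "linear")
  expect_true(all(abs(up$values - 0.7) < 1e-12))
  expect_equal(up$spacing_mm, c(1, 1, 5))

  lab <- label_volume(array(sample(c(0L, 1L, 3L), 20 * 20 * 3, TRUE),
                            c(20, 20, 3)), c(1, 1, 5))
  res <- resample_inplane(lab, c(33, 17))
  expect_true(all(unique(as.vector(res$values)) %in% c(0L, 1L, 3L)))
  expect_error(resample_inplane(lab, c(32, 32), "linear"), "nearest")
})

test_that("clip-normalize matches a sort-based percentile oracle", {
  set.seed(4)
  vals <- sample(1:1000)
  v <- volume_grid(array(vals, c(10, 10, 10)), c(1, 1, 1))
  out <- clip_normalize(v)$values
  srt <- sort(vals)
  lo <- srt[5]; hi <- srt[996]   # ~0.5 and ~99.5 percent ranks
  expect_true(all(out[v$values <= lo - 1] == 0))
  expect_true(all(out[v$values >= hi + 1] == 1))
  expect_true(min(out) == 0 && max(out) == 1)
  # monotone among unclipped voxels
  mid <- v$values > lo + 1 & v$values < hi - 1
  expect_true(all(diff(out[mid][order(v$values[mid])]) >= 0))

  expect_warning(z <- clip_normalize(volume_grid(array(2, c(4, 4, 2)),
                                                 c(1, 1, 1))),
                 "degenerate")
  expect_true(all(z$values == 0))

  # percentiles restricted to a mask
  m <- label_volume(array(as.integer(vals > 500), c(10, 10, 10)), c(1, 1, 1))
  om <- clip_normalize(v, mask = m)$values
  expect_true(all(om[v$values <= 500] == 0))
})

test_that("patch planning snaps the last start to the volume edge", {
  specs <- plan_patches(c(512L, 8L, 8L), c(192L, 8L, 8L), 0.5, "uniform")
  xs <- sort(unique(vapply(specs, function(s) s$start[1], integer(1))))
  expect_equal(xs, c(0L, 96L, 192L, 288L, 320L))
  one <- plan_patches(c(64L, 64L, 8L), c(64L, 64L, 8L), 0.5)
  expect_length(one, 1L)
  expect_equal(one[[1]]$start, c(0L, 0L, 0L))
  expect_error(plan_patches(c(8L, 8L, 8L), c(0L, 8L, 8L)), "positive")
  expect_warning(plan_patches(c(8L, 8L, 4L), c(16L, 8L, 8L)), "snapping")
})

test_that("every voxel is covered for random patch plans", {
  set.seed(7)
  for (i in 1:50) {
    shape <- sample(5:40, 3, replace = TRUE)
    patch <- pmin(shape, sample(3:24, 3, replace = TRUE))
    ov <- sample(c(0, 0.25, 0.5), 1)
    specs <- plan_patches(shape, patch, ov, "uniform")
    cov <- array(0L, shape)
    for (s in specs) {
      cov[(s$start[1] + 1):(s$start[1] + s$size[1]),
          (s$start[2] + 1):(s$start[2] + s$size[2]),
          (s$start[3] + 1):(s$start[3] + s$size[3])] <- 1L
    }
    expect_true(all(cov == 1L))
  }
})

test_that("assembling identity patch outputs reconstructs the volume", {
  set.seed(8)
  vol <- array(runif(40 * 36 * 10), c(40, 36, 10))
  for (w in c("uniform", "gaussian")) {
    specs <- plan_patches(dim(vol), c(16L, 16L, 6L), 0.5, w)
    outs <- lapply(specs, function(s) list(spec = s,
                                           values = extract_patch(vol, s)))
    rec <- assemble(outs, dim(vol))
    expect_lt(max(abs(rec - vol)), 1e-6)
  }
  # hand-computed overlap average: constant patches 0 and 1, uniform weights
  s1 <- structure(list(start = c(0L, 0L, 0L), size = c(4L, 4L, 2L),
                       weight_map = array(1, c(4, 4, 2))), class = "patch_spec")
  s2 <- structure(list(start = c(2L, 0L, 0L), size = c(4L, 4L, 2L),
                       weight_map = array(1, c(4, 4, 2))), class = "patch_spec")
  out <- assemble(list(list(spec = s1, values = array(0, c(4, 4, 2))),
                       list(spec = s2, values = array(1, c(4, 4, 2)))),
                  c(6L, 4L, 2L))
  expect_true(all(out[3:4, , ] == 0.5))
  expect_true(all(out[1:2, , ] == 0) && all(out[5:6, , ] == 1))
})

test_that("augmentation is identity-safe, label-preserving and involutive", {
  cfg <- small_phantom(seed = 21)
  cs <- generate_case(cfg)
  idp <- augment_params(flip_prob_per_axis = 0, max_rotation_deg = 0,
                        intensity_scale_range = c(1, 1))
  out <- augment(cs$image, cs$lesion_label, idp)
  expect_identical(out$image$values, cs$image$values)
  expect_identical(out$label$values, cs$lesion_label$values)

  rp <- augment_params(seed = 99)
  out2 <- augment(cs$image, cs$lesion_label, rp)
  expect_true(all(unique(as.vector(out2$label$values)) %in%
                  c(0L, unique(as.vector(cs$lesion_label$values)))))
  # deterministic under seed
  out3 <- augment(cs$image, cs$lesion_label, rp)
  expect_identical(out2$image$values, out3$image$values)

  # flips alone preserve foreground count exactly and are involutive
  fp <- augment_params(flip_prob_per_axis = 1, max_rotation_deg = 0,
                       intensity_scale_range = c(1, 1))
  f1 <- augment(cs$image, cs$lesion_label, fp)
  expect_equal(sum(f1$label$values > 0), sum(cs$lesion_label$values > 0))
  f2 <- augment(f1$image, f1$label, fp)
  expect_identical(f2$image$values, cs$image$values)
  expect_identical(f2$label$values, cs$lesion_label$values)
})

test_that("2.5D slabs replicate edges and reconstruct the volume", {
  v <- array(seq_len(6 * 6 * 10), c(6, 6, 10))
  sl <- make_2p5d_slabs(v, 5)
  expect_equal(dim(sl$slabs), c(6, 6, 5, 10))
  # first slab: slices (1,1,1,2,3) in 1-based terms
  expect_identical(sl$slabs[, , 1, 1], v[, , 1] + 0)
  expect_identical(sl$slabs[, , 2, 1], v[, , 1] + 0)
  expect_identical(sl$slabs[, , 5, 1], v[, , 3] + 0)
  # a middle slab holds the five surrounding slices exactly
  for (j in 1:5) expect_identical(sl$slabs[, , j, 6], v[, , 3 + j] + 0)
  # center channels reconstruct the volume
  rec <- array(0, dim(v))
  for (c0 in 1:10) rec[, , c0] <- sl$slabs[, , 3, c0]
  expect_identical(rec, v + 0)
  expect_error(make_2p5d_slabs(v, 4), "odd")
})
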