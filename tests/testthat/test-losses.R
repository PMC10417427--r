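test_that("the Tversky index reproduces hand-counted confusion examples", {
  # 2x2 toy masks: TP=2, FP=1, FN=1
  pred <- c(1, 1, 1, 0)
  target <- c(1, 1, 0, 1)
  cfg <- tversky_config(alpha = 0.7, beta = 0.3, smooth = 1e-12)
  expect_equal(soft_tversky_index(pred, target, cfg), 2 / 3,
               tolerance = 1e-9)
  expect_equal(focal_tversky_loss(pred, target,
                                  tversky_config(0.7, 0.3, gamma = 1,
                                                 smooth = 1e-12)),
               1 / 3, tolerance = 1e-9)
  expect_equal(focal_tversky_loss(pred, target,
                                  tversky_config(0.7, 0.3, gamma = 0.75,
                                                 smooth = 1e-12)),
               (1 / 3)^0.75, tolerance = 1e-9)
  # perfect overlap
  expect_equal(soft_tversky_index(target, target, cfg), 1, tolerance = 1e-9)
  expect_lt(focal_tversky_loss(target, target, tversky_config()), 1e-6)
  expect_error(soft_tversky_index(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("alpha = beta = 0.5 recovers the soft Dice coefficient", {
  set.seed(31)
  cfg <- tversky_config(0.5, 0.5, smooth = 1e-12)
  for (i in 1:20) {
    p <- runif(60)
    g <- as.numeric(runif(60) < 0.4)
    sd <- 2 * sum(p * g) / (sum(p) + sum(g))
    expect_equal(soft_tversky_index(p, g, cfg), sd, tolerance = 1e-9)
  }
})

test_that("loss is monotone in the confusion counts and bounded", {
  cfg <- tversky_config(0.7, 0.3, gamma = 0.75, smooth = 1e-9)
  loss_counts <- function(tp, fp, fn) {
    pred <- c(rep(1, tp), rep(1, fp), rep(0, fn))
    tgt <- c(rep(1, tp), rep(0, fp), rep(1, fn))
    focal_tversky_loss(pred, tgt, cfg)
  }
  for (fp in 0:2) for (fn in 0:2) {
    if (fp + fn == 0) next
    expect_gt(loss_counts(1, fp, fn), loss_counts(2, fp, fn))
    expect_gt(loss_counts(2, fp, fn), loss_counts(3, fp, fn))
  }
  for (tp in 1:3) {
    expect_lt(loss_counts(tp, 0, 1), loss_counts(tp, 1, 1))
    expect_lt(loss_counts(tp, 1, 0), loss_counts(tp, 1, 1))
  }
  set.seed(32)
  for (i in 1:20) {
    l <- focal_tversky_loss(runif(30), as.numeric(runif(30) < 0.5), cfg)
    expect_gte(l, 0)
    expect_lte(l, 1)
  }
})

test_that("the focal exponent sharpens the gradient near a perfect index", {
  # |d loss / d TI| at TI -> 1 grows for gamma < 1 relative to gamma = 1
  h <- 1e-6
  slope <- function(gamma, ti) {
    (( (1 - (ti + h))^gamma) - ((1 - (ti - h))^gamma)) / (2 * h)
  }
  expect_gt(abs(slope(0.75, 0.999)), abs(slope(1, 0.999)))
  expect_gt(abs(slope(0.75, 0.999)) / abs(slope(1, 0.999)),
            abs(slope(0.75, 0.9)) / abs(slope(1, 0.9)))
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(33)
  ns <- asNamespace("csrseg")
  p <- runif(25, 0.05, 0.95)
  g <- as.numeric(runif(25) < 0.4)
  cfg <- tversky_config(0.7, 0.3, gamma = 0.75)
  an <- ns$focal_tversky_grad(p, g, cfg)
  eps <- 1e-6
  for (i in sample(25, 6)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (focal_tversky_loss(pp, g, cfg) - focal_tversky_loss(pm, g, cfg)) /
      (2 * eps)
    expect_equal(an[i], fd, tolerance = 1e-5)
  }
})
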