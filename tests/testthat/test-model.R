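ns <- asNamespace("csrseg")

test_that("squeeze-and-excitation gates behave as channel attention", {
  set.seed(61)
  x <- matrix(rnorm(200 * 6), 200, 6)
  w <- se_weights(6, reduction = 2)
  # forcing the excitation toward 1 recovers the input
  w1 <- w
  w1$W1[] <- 0; w1$W2[] <- 0; w1$b1[] <- 0; w1$b2[] <- 40
  expect_lt(max(abs(se_block(x, weights = w1) - x)), 1e-10)
  # sigmoid gate: per-channel output magnitude strictly below input
  y <- se_block(x, weights = w)
  for (ch in 1:6) {
    expect_lt(max(abs(y[, ch])), max(abs(x[, ch])) + 1e-12)
  }
  # constant channels pool to exactly those constants
  consts <- c(0.3, -1.2, 2.5)
  xc <- matrix(rep(consts, each = 50), 50, 3)
  sq <- ns$nn_se_fwd(xc, diag(3), rep(0, 3), diag(3), rep(0, 3))
  expect_equal(sq$m, consts)
})

test_that("CSR blocks preserve shape and omit the projection when square", {
  set.seed(62)
  x <- matrix(rnorm(8 * 8 * 4 * 3), 8 * 8 * 4, 3)
  r <- csr_block(x, c(8L, 8L, 4L), in_C = 3, out_C = 3)
  expect_equal(dim(r$y), dim(x))
  expect_true(all(is.finite(r$y)))
  expect_false("proj.W" %in% names(r$weights))
  r2 <- csr_block(x, c(8L, 8L, 4L), in_C = 3, out_C = 5)
  expect_equal(ncol(r2$y), 5)
  expect_true("proj.W" %in% names(r2$weights))
})

test_that("network outputs preserve spatial shape for awkward input sizes", {
  cfg <- model_config("3D", base_channels = 4, depth = 2, se_reduction = 2,
                      z_pools = 1)
  m <- build_csr_unet(cfg, seed = 3)
  for (d in list(c(16L, 16L, 8L), c(20L, 12L, 5L), c(9L, 13L, 4L))) {
    out <- unet_apply(m, array(rnorm(prod(d)), d))
    expect_equal(dim(out$prob), d)
    expect_true(all(out$prob >= 0 & out$prob <= 1))
  }
  cfg2 <- model_config("2.5D", base_channels = 4, depth = 2, se_reduction = 2)
  m2 <- build_csr_unet(cfg2, seed = 3)
  slab <- array(rnorm(24 * 18 * 5), c(24, 18, 5))
  out2 <- unet_apply(m2, slab)
  expect_equal(dim(out2$prob), c(24L, 18L))
})

test_that("builds are deterministic and eval-mode forwards reproducible", {
  cfg <- model_config("3D", base_channels = 4, depth = 2, se_reduction = 2)
  a <- build_csr_unet(cfg, seed = 11)
  b <- build_csr_unet(cfg, seed = 11)
  expect_identical(a$params, b$params)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_identical(unet_apply(a, x)$prob, unet_apply(a, x)$prob)
})

test_that("gradients reach every parameter and match finite differences", {
  set.seed(63)
  cfg <- model_config("3D", base_channels = 4, depth = 2, se_reduction = 2,
                      z_pools = 1)
  m <- build_csr_unet(cfg, seed = 7)
  dims <- c(6L, 6L, 4L)
  x <- matrix(rnorm(prod(dims)), prod(dims), 1)
  tgt <- as.numeric(runif(prod(dims)) < 0.3)
  lcfg <- tversky_config()
  fw <- ns$unet_forward(m, x, dims, train = TRUE)
  probs <- ns$nn_softmax(fw$logits)
  dp <- ns$focal_tversky_grad(probs[, 2], tgt, lcfg)
  dlog <- ns$nn_softmax_bwd(probs, cbind(0, as.numeric(dp)))
  gr <- ns$unet_backward(m, fw, dlog)
  expect_setequal(names(gr), names(m$params))
  for (nm in names(m$params)) {
    expect_gt(max(abs(gr[[nm]])), 0)
  }
  loss_of <- function(params) {
    m2 <- m
    m2$params <- params
    m2$bn <- new.env()
    fw2 <- ns$unet_forward(m2, x, dims, train = TRUE)
    focal_tversky_loss(ns$nn_softmax(fw2$logits)[, 2], tgt, lcfg)
  }
  eps <- 1e-5
  set.seed(64)
  for (nm in sample(names(m$params), 8)) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(gr[[nm]][i], fd, tolerance = 1e-3)
  }
})

test_that("a CSR network overfits one sample to a fraction of initial loss", {
  set.seed(65)
  cfg <- model_config("3D", base_channels = 4, depth = 2, se_reduction = 2,
                      z_pools = 1)
  m <- build_csr_unet(cfg, seed = 13)
  dims <- c(16L, 16L, 6L)
  arr <- array(0.1, dims)
  tgt <- array(0, dims)
  tgt[6:11, 6:11, 3:4] <- 1
  arr[tgt == 1] <- 0.9
  x <- matrix(as.numeric(arr), prod(dims), 1)
  lcfg <- tversky_config()
  opt <- ns$adam_init(m$params)
  losses <- numeric(200)
  for (it in 1:200) {
    fw <- ns$unet_forward(m, x, dims, train = TRUE)
    probs <- ns$nn_softmax(fw$logits)
    losses[it] <- focal_tversky_loss(probs[, 2], as.numeric(tgt), lcfg)
    dp <- ns$focal_tversky_grad(probs[, 2], as.numeric(tgt), lcfg)
    dlog <- ns$nn_softmax_bwd(probs, cbind(0, as.numeric(dp)))
    gr <- ns$unet_backward(m, fw, dlog)
    m$params <- ns$adam_step(opt, m$params, gr, 1e-3)
  }
  expect_lt(losses[200], 0.1 * losses[1])
})
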