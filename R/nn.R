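# Compact neural-network engine used by the CSR-UNet models. Feature maps
# are (n_voxel x n_channel) matrices in R-array voxel order (x fastest),
# with spatial dims carried alongside; convolutions are same-padded and
# BLAS-backed (im2col + gemm in C++). Every layer has an explicit backward
# pass; the whole network gradient is assembled by hand in model.R.

nn_conv_fwd <- function(x, dims, W, b, ksz) {
  if (all(ksz == 1L)) {
    out <- x %*% W
    out <- sweep(out, 2, b, "+")
    return(out)
  }
  cs_conv_fwd(x, as.integer(dims), W, as.numeric(b), as.integer(ksz))
}

nn_conv_bwd <- function(x, dims, W, ksz, dout) {
  if (all(ksz == 1L)) {
    return(list(dx = dout %*% t(W), dW = crossprod(x, dout),
                db = colSums(dout)))
  }
  r <- cs_conv_bwd(x, as.integer(dims), W, as.integer(ksz), dout)
  r$db <- as.numeric(r$db)
  r
}

nn_relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

nn_relu_bwd <- function(x, dy) {
  dy[x <= 0] <- 0
  dy
}

# batch normalization over voxels, per channel. state is an environment
# slot holding running mean/var for eval mode.
nn_bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.9,
                      eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    va <- colMeans(x^2) - mu^2
    va[va < 0] <- 0
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- va
    } else {
      state$mean <- momentum * state$mean + (1 - momentum) * mu
      state$var <- momentum * state$var + (1 - momentum) * va
    }
  } else {
    mu <- if (is.null(state$mean)) rep(0, ncol(x)) else state$mean
    va <- if (is.null(state$var)) rep(1, ncol(x)) else state$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, invstd = invstd)
}

nn_bn_bwd <- function(cache, gamma, dy) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2, t1 / n, "-") -
    sweep(cache$xhat, 2, t2 / n, "*")
  dx <- sweep(dx, 2, cache$invstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# squeeze-and-excitation: per-channel gate from globally pooled statistics
nn_se_fwd <- function(x, W1, b1, W2, b2) {
  m <- colMeans(x)                       # squeeze
  u1 <- drop(m %*% W1) + b1
  h1 <- pmax(u1, 0)
  u2 <- drop(h1 %*% W2) + b2
  s <- sigmoid(u2)                       # excitation gate in (0,1)
  y <- sweep(x, 2, s, "*")
  list(y = y, m = m, u1 = u1, h1 = h1, s = s)
}

nn_se_bwd <- function(x, cache, W1, W2, dy) {
  n <- nrow(x)
  dx <- sweep(dy, 2, cache$s, "*")
  ds <- colSums(dy * x)
  du2 <- ds * cache$s * (1 - cache$s)
  dW2 <- outer(cache$h1, du2)
  db2 <- du2
  dh1 <- drop(W2 %*% du2)
  du1 <- dh1 * (cache$u1 > 0)
  dW1 <- outer(cache$m, du1)
  db1 <- du1
  dm <- drop(W1 %*% du1)
  dx <- dx + matrix(dm / n, n, length(dm), byrow = TRUE)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# index map: low-res row -> high-res row for one pooling/upsampling offset
grid_offset_index <- function(dims_lo, dims_hi, f, off) {
  n2 <- prod(dims_lo)
  r <- 0:(n2 - 1)
  i <- r %% dims_lo[1]
  j <- (r %/% dims_lo[1]) %% dims_lo[2]
  k <- r %/% (dims_lo[1] * dims_lo[2])
  (f[1] * i + off[1]) + dims_hi[1] * ((f[2] * j + off[2]) +
                                       dims_hi[2] * (f[3] * k + off[3])) + 1
}

offset_grid <- function(f) {
  as.matrix(expand.grid(ox = 0:(f[1] - 1), oy = 0:(f[2] - 1),
                        oz = 0:(f[3] - 1), KEEP.OUT.ATTRS = FALSE))
}

nn_maxpool_fwd <- function(x, dims, f) {
  dims_lo <- dims %/% f
  offs <- offset_grid(f)
  n2 <- prod(dims_lo)
  C <- ncol(x)
  best <- NULL
  bestidx <- NULL
  for (o in seq_len(nrow(offs))) {
    idx <- grid_offset_index(dims_lo, dims, f, offs[o, ])
    cand <- x[idx, , drop = FALSE]
    if (is.null(best)) {
      best <- cand
      bestidx <- matrix(idx, n2, C)
    } else {
      m <- cand > best
      best[m] <- cand[m]
      im <- matrix(idx, n2, C)
      bestidx[m] <- im[m]
    }
  }
  list(y = best, argmax = bestidx, dims_lo = dims_lo)
}

nn_maxpool_bwd <- function(cache, dims, C, dy) {
  dx <- matrix(0, prod(dims), C)
  n <- prod(dims)
  lin <- cache$argmax + matrix((0:(C - 1)) * n, nrow(dy), C, byrow = TRUE)
  dx[lin] <- dy
  dx
}

# transposed convolution with kernel == stride: each output voxel receives
# exactly one input contribution. W has dim (C_in, C_out, prod(f)).
# bias-free: the result feeds a batch-normalized block.
nn_upconv_fwd <- function(x, dims_lo, f, W) {
  dims_hi <- dims_lo * f
  offs <- offset_grid(f)
  out <- matrix(0, prod(dims_hi), dim(W)[2])
  for (o in seq_len(nrow(offs))) {
    idx <- grid_offset_index(dims_lo, dims_hi, f, offs[o, ])
    out[idx, ] <- x %*% W[, , o]
  }
  out
}

nn_upconv_bwd <- function(x, dims_lo, f, W, dout) {
  dims_hi <- dims_lo * f
  offs <- offset_grid(f)
  dx <- matrix(0, nrow(x), dim(W)[1])
  dW <- array(0, dim(W))
  for (o in seq_len(nrow(offs))) {
    idx <- grid_offset_index(dims_lo, dims_hi, f, offs[o, ])
    dsub <- dout[idx, , drop = FALSE]
    dx <- dx + dsub %*% t(W[, , o])
    dW[, , o] <- crossprod(x, dsub)
  }
  list(dx = dx, dW = dW, db = colSums(dout))
}

# zero-pad / crop a feature-map matrix to new spatial dims (high end)
pad_rows_index <- function(dims, nd) {
  ii <- seq_len(dims[1])
  jj <- seq_len(dims[2])
  kk <- seq_len(dims[3])
  as.vector(outer(outer(ii, (jj - 1) * nd[1], "+"),
                  (kk - 1) * nd[1] * nd[2], "+"))
}

nn_pad_fm <- function(x, dims, nd) {
  if (all(nd == dims)) return(x)
  out <- matrix(0, prod(nd), ncol(x))
  out[pad_rows_index(dims, nd), ] <- x
  out
}

nn_crop_fm <- function(x, nd, dims) {
  if (all(nd == dims)) return(x)
  x[pad_rows_index(dims, nd), , drop = FALSE]
}

# two-class softmax over channels; returns probabilities
nn_softmax <- function(logits) {
  mx <- logits[, 1]
  for (j in seq_len(ncol(logits))[-1]) mx <- pmax(mx, logits[, j])
  e <- exp(logits - mx)
  e / rowSums(e)
}

# gradient of loss wrt logits given gradient wrt probabilities
nn_softmax_bwd <- function(probs, dprobs) {
  s <- rowSums(dprobs * probs)
  probs * (dprobs - s)
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  st$v <- st$m
  st$t <- 0L
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1
  b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + state$eps)
  }
  params
}

#' Cosine-annealed learning rate schedule
#'
#' `lr(t) = lr0 * (1 + cos(pi * t / T)) / 2` for epoch t in 0..T-1; the
#' rate decays from `lr0` to near zero over `epochs`.
#'
#' @param lr0 initial learning rate.
#' @param epoch 1-based epoch number.
#' @param epochs total epochs.
#' @return Learning rate for the epoch.
#' @export
cosine_lr <- function(lr0, epoch, epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / epochs))
}
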