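# CSR-UNet: a U-Net whose convolution blocks are CSR blocks -- dual 3x3
# (x3) convolutions with batch normalization, squeeze-and-excitation
# channel attention after the second convolution, and a residual shortcut
# (identity, or a 1x1 projection when channel counts differ). The 3D
# variant consumes single-channel volumes with 3x3x3 kernels; the 2.5D
# variant consumes k-slice slabs as channels with 3x3 kernels and predicts
# the slab's center slice.

#' CSR-UNet model configuration
#'
#' @param dims "3D" or "2.5D".
#' @param in_channels input channels: 1 for 3D volumes, the slab thickness
#'   (default 5) for 2.5D.
#' @param out_channels output classes (default 2: background/lesion).
#' @param base_channels first-stage width (default 16).
#' @param depth number of downsamplings (default 4).
#' @param se_reduction squeeze-and-excitation bottleneck reduction.
#' @param z_pools number of stages that also pool the slice axis (3D only;
#'   the earliest `depth - z_pools` stages keep the slice axis, which suits
#'   anisotropic volumes with few slices). Default: all stages.
#' @return A `model_config` object.
#' @export
model_config <- function(dims = c("3D", "2.5D"), in_channels = NULL,
                         out_channels = 2L, base_channels = 16L,
                         depth = 4L, se_reduction = 4L, z_pools = depth) {
  dims <- match.arg(dims)
  if (is.null(in_channels)) in_channels <- if (dims == "3D") 1L else 5L
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, base_channels >= 1L, out_channels >= 1L,
            se_reduction >= 1L, base_channels >= se_reduction)
  z_pools <- if (dims == "2.5D") 0L else as.integer(min(z_pools, depth))
  structure(list(dims = dims, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_channels = as.integer(base_channels), depth = depth,
                 se_reduction = as.integer(se_reduction),
                 z_pools = z_pools), class = "model_config")
}

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(rnorm(nrow_ * ncol_, 0, sqrt(2 / fan_in)), nrow_, ncol_)
}

#' Initialize squeeze-and-excitation weights
#'
#' @param channels number of feature channels C.
#' @param reduction bottleneck reduction; hidden width is
#'   `max(1, floor(C / reduction))`.
#' @return list with `W1`, `b1`, `W2`, `b2`.
#' @export
se_weights <- function(channels, reduction = 4L) {
  h <- max(1L, channels %/% reduction)
  # zero squeeze weights + small positive bias: every hidden unit starts
  # active (pooled features are non-negative after relu, so a random W1
  # can leave the whole bottleneck relu-dead); the random excitation
  # layer breaks the symmetry and the gate starts near 0.5
  list(W1 = matrix(0, channels, h), b1 = rep(0.1, h),
       W2 = he_init(h, channels, h), b2 = rep(0, channels))
}

#' Apply a squeeze-and-excitation block
#'
#' Scales each channel of `features` by
#' `s = sigmoid(W2 relu(W1 globalavgpool(features)))`, a per-channel gate
#' strictly inside (0, 1).
#'
#' @param features feature map as an (n_voxel x C) matrix.
#' @param reduction bottleneck reduction used when `weights` is NULL.
#' @param weights optional weight list as from [se_weights()].
#' @return Matrix of the same shape as `features`.
#' @export
se_block <- function(features, reduction = 4L, weights = NULL) {
  stopifnot(is.matrix(features))
  if (is.null(weights)) weights <- se_weights(ncol(features), reduction)
  nn_se_fwd(features, weights$W1, weights$b1, weights$W2, weights$b2)$y
}

csr_weights <- function(in_C, out_C, ksz, se_reduction) {
  K <- prod(ksz)
  # convolutions feeding batch norm carry no bias: the normalization
  # subtracts any per-channel constant, so such biases would be dead
  p <- list(
    "conv1.W" = he_init(in_C * K, out_C, in_C * K),
    "bn1.gamma" = rep(1, out_C), "bn1.beta" = rep(0, out_C),
    "conv2.W" = he_init(out_C * K, out_C, out_C * K),
    "bn2.gamma" = rep(1, out_C), "bn2.beta" = rep(0, out_C))
  se <- se_weights(out_C, se_reduction)
  p[["se.W1"]] <- se$W1; p[["se.b1"]] <- se$b1
  p[["se.W2"]] <- se$W2; p[["se.b2"]] <- se$b2
  if (in_C != out_C) {
    p[["proj.W"]] <- he_init(in_C, out_C, in_C)
    p[["proj.b"]] <- rep(0, out_C)
  }
  p
}

csr_forward <- function(x, dims, p, bn1, bn2, ksz, train) {
  a1 <- nn_conv_fwd(x, dims, p[["conv1.W"]], rep(0, ncol(p[["conv1.W"]])), ksz)
  n1 <- nn_bn_fwd(a1, p[["bn1.gamma"]], p[["bn1.beta"]], bn1, train)
  r1 <- nn_relu_fwd(n1$y)
  a2 <- nn_conv_fwd(r1, dims, p[["conv2.W"]], rep(0, ncol(p[["conv2.W"]])), ksz)
  n2 <- nn_bn_fwd(a2, p[["bn2.gamma"]], p[["bn2.beta"]], bn2, train)
  r2 <- nn_relu_fwd(n2$y)
  se <- nn_se_fwd(r2, p[["se.W1"]], p[["se.b1"]], p[["se.W2"]], p[["se.b2"]])
  shortcut <- if (is.null(p[["proj.W"]])) x else
    nn_conv_fwd(x, dims, p[["proj.W"]], p[["proj.b"]], c(1L, 1L, 1L))
  y <- se$y + shortcut
  list(y = y,
       cache = list(x = x, n1 = n1, r1 = r1, n2 = n2, r2 = r2, se = se))
}

csr_backward <- function(dy, dims, p, cache, ksz) {
  g <- list()
  seb <- nn_se_bwd(cache$r2, cache$se, p[["se.W1"]], p[["se.W2"]], dy)
  g[["se.W1"]] <- seb$dW1; g[["se.b1"]] <- seb$db1
  g[["se.W2"]] <- seb$dW2; g[["se.b2"]] <- seb$db2
  dr2 <- nn_relu_bwd(cache$n2$y, seb$dx)
  bn2 <- nn_bn_bwd(cache$n2, p[["bn2.gamma"]], dr2)
  g[["bn2.gamma"]] <- bn2$dgamma; g[["bn2.beta"]] <- bn2$dbeta
  cv2 <- nn_conv_bwd(cache$r1, dims, p[["conv2.W"]], ksz, bn2$dx)
  g[["conv2.W"]] <- cv2$dW
  dr1 <- nn_relu_bwd(cache$n1$y, cv2$dx)
  bn1 <- nn_bn_bwd(cache$n1, p[["bn1.gamma"]], dr1)
  g[["bn1.gamma"]] <- bn1$dgamma; g[["bn1.beta"]] <- bn1$dbeta
  cv1 <- nn_conv_bwd(cache$x, dims, p[["conv1.W"]], ksz, bn1$dx)
  g[["conv1.W"]] <- cv1$dW
  dx <- cv1$dx
  if (is.null(p[["proj.W"]])) {
    dx <- dx + dy
  } else {
    pr <- nn_conv_bwd(cache$x, dims, p[["proj.W"]], c(1L, 1L, 1L), dy)
    g[["proj.W"]] <- pr$dW; g[["proj.b"]] <- pr$db
    dx <- dx + pr$dx
  }
  list(dx = dx, grads = g)
}

#' Apply a stand-alone CSR block
#'
#' Functional form of the CSR block (dual same-padded convolutions with
#' batch normalization, SE attention, residual shortcut) for inspection
#' and testing outside a full network.
#'
#' @param x feature map, (n_voxel x in_C) matrix.
#' @param dims integer(3) spatial dims of `x`.
#' @param in_C,out_C channel counts; `in_C != out_C` adds a 1x1 projection
#'   shortcut.
#' @param ksz kernel size, default c(3, 3, 3).
#' @param se_reduction SE reduction.
#' @param weights optional parameter list from a previous call (element
#'   `weights` of the result), for reproducible application.
#' @param train logical; use batch statistics for normalization.
#' @return list with `y` (output feature map) and `weights`.
#' @export
csr_block <- function(x, dims, in_C = ncol(x), out_C = in_C,
                      ksz = c(3L, 3L, 3L), se_reduction = 4L,
                      weights = NULL, train = TRUE) {
  stopifnot(is.matrix(x), ncol(x) == in_C)
  if (is.null(weights)) weights <- csr_weights(in_C, out_C, ksz, se_reduction)
  bn1 <- new.env(parent = emptyenv())
  bn2 <- new.env(parent = emptyenv())
  r <- csr_forward(x, dims, weights, bn1, bn2, as.integer(ksz), train)
  list(y = r$y, weights = weights)
}

get_bn <- function(model, name) {
  if (is.null(model$bn[[name]])) {
    model$bn[[name]] <- new.env(parent = emptyenv())
  }
  model$bn[[name]]
}

#' Build a CSR-UNet
#'
#' Encoder of `depth` CSR stages with 2x max-pool downsampling and channel
#' doubling from `base_channels`; symmetric decoder with transposed-conv
#' upsampling, skip concatenations and CSR stages; final 1x1 convolution
#' to `out_channels`. Inputs whose spatial shape is not divisible by the
#' pooling product are zero-padded internally and the output cropped back,
#' so the output spatial shape always equals the input shape.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization; two builds with the
#'   same config and seed are identical.
#' @return A `csr_unet` model object (config, flat parameter list, batch
#'   norm state).
#' @export
build_csr_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(as.integer(seed))
  ksz <- if (config$dims == "3D") c(3L, 3L, 3L) else c(3L, 3L, 1L)
  D <- config$depth
  B <- config$base_channels
  widths <- B * 2^(0:(D))           # widths[s] = stage s, widths[D+1] = bottleneck
  params <- list()
  add <- function(prefix, pl) {
    for (k in names(pl)) params[[paste(prefix, k, sep = "/")]] <<- pl[[k]]
  }
  in_C <- config$in_channels
  for (s in seq_len(D)) {
    add(paste0("enc", s), csr_weights(in_C, widths[s], ksz, config$se_reduction))
    in_C <- widths[s]
  }
  add("bot", csr_weights(widths[D], widths[D + 1], ksz, config$se_reduction))
  for (s in rev(seq_len(D))) {
    f <- stage_factor(config, s)
    up_in <- if (s == D) widths[D + 1] else widths[s + 1]
    params[[paste0("up", s, "/W")]] <-
      array(rnorm(up_in * widths[s] * prod(f), 0, sqrt(2 / up_in)),
            c(up_in, widths[s], prod(f)))
    add(paste0("dec", s),
        csr_weights(2L * widths[s], widths[s], ksz, config$se_reduction))
  }
  params[["final/W"]] <- he_init(B, config$out_channels, B)
  params[["final/b"]] <- rep(0, config$out_channels)
  structure(list(config = config, params = params, ksz = ksz,
                 bn = new.env(parent = emptyenv())),
            class = "csr_unet")
}

stage_factor <- function(config, s) {
  fz <- if (config$dims == "2.5D") 1L else
    if (s > config$depth - config$z_pools) 2L else 1L
  c(2L, 2L, fz)
}

sub_params <- function(params, prefix) {
  keys <- grep(paste0("^", prefix, "/"), names(params), value = TRUE)
  setNames(params[keys], sub(paste0("^", prefix, "/"), "", keys))
}

model_divisor <- function(config) {
  d <- prod(rep(2L, config$depth))
  zd <- if (config$z_pools > 0L) 2L^config$z_pools else 1L
  c(d, d, zd)
}

#' @export
print.csr_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<csr_unet %s, depth %d, base %d, %d parameters>\n",
              x$config$dims, x$config$depth, x$config$base_channels,
              as.integer(np)))
  invisible(x)
}

# forward pass; x is (n_voxel x in_channels), dims its spatial shape
unet_forward <- function(model, x, dims, train = FALSE) {
  cfg <- model$config
  dims <- as.integer(dims)
  dv <- model_divisor(cfg)
  nd <- as.integer(ceiling(dims / dv) * dv)
  x <- nn_pad_fm(x, dims, nd)
  cur <- nd
  caches <- list()
  skips <- list()
  for (s in seq_len(cfg$depth)) {
    p <- sub_params(model$params, paste0("enc", s))
    r <- csr_forward(x, cur, p, get_bn(model, paste0("enc", s, ".bn1")),
                     get_bn(model, paste0("enc", s, ".bn2")), model$ksz, train)
    skips[[s]] <- r$y
    caches[[paste0("enc", s)]] <- r$cache
    f <- stage_factor(cfg, s)
    pl <- nn_maxpool_fwd(r$y, cur, f)
    caches[[paste0("pool", s)]] <- list(pl = pl, dims = cur, f = f,
                                        C = ncol(r$y))
    x <- pl$y
    cur <- pl$dims_lo
  }
  p <- sub_params(model$params, "bot")
  r <- csr_forward(x, cur, p, get_bn(model, "bot.bn1"),
                   get_bn(model, "bot.bn2"), model$ksz, train)
  caches[["bot"]] <- r$cache
  x <- r$y
  for (s in rev(seq_len(cfg$depth))) {
    f <- stage_factor(cfg, s)
    W <- model$params[[paste0("up", s, "/W")]]
    up <- nn_upconv_fwd(x, cur, f, W)
    caches[[paste0("up", s)]] <- list(x = x, dims_lo = cur, f = f)
    cur <- cur * f
    xc <- cbind(up, skips[[s]])
    p <- sub_params(model$params, paste0("dec", s))
    r <- csr_forward(xc, cur, p, get_bn(model, paste0("dec", s, ".bn1")),
                     get_bn(model, paste0("dec", s, ".bn2")), model$ksz, train)
    caches[[paste0("dec", s)]] <- r$cache
    x <- r$y
  }
  logits_pad <- nn_conv_fwd(x, cur, model$params[["final/W"]],
                            model$params[["final/b"]], c(1L, 1L, 1L))
  caches[["final"]] <- list(x = x)
  logits <- nn_crop_fm(logits_pad, nd, dims)
  list(logits = logits, cache = list(stages = caches, dims = dims, nd = nd))
}

# backward pass; dlogits matches the cropped logits
unet_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  caches <- fw$cache$stages
  dims <- fw$cache$dims
  nd <- fw$cache$nd
  grads <- list()
  dl <- matrix(0, prod(nd), ncol(dlogits))
  dl[pad_rows_index(dims, nd), ] <- dlogits
  fx <- caches[["final"]]$x
  grads[["final/W"]] <- crossprod(fx, dl)
  grads[["final/b"]] <- colSums(dl)
  dx <- dl %*% t(model$params[["final/W"]])
  # recompute decoder dims sequence
  dims_at <- list()
  c2 <- nd
  for (s in seq_len(cfg$depth)) {
    dims_at[[paste0("enc", s)]] <- c2
    c2 <- c2 %/% stage_factor(cfg, s)
  }
  dims_at[["bot"]] <- c2
  dskips <- vector("list", cfg$depth)
  for (s in seq_len(cfg$depth)) {
    dd <- dims_at[[paste0("enc", s)]]
    p <- sub_params(model$params, paste0("dec", s))
    bk <- csr_backward(dx, dd, p, caches[[paste0("dec", s)]], model$ksz)
    for (k in names(bk$grads)) grads[[paste(paste0("dec", s), k, sep = "/")]] <- bk$grads[[k]]
    upc <- caches[[paste0("up", s)]]
    Wup <- model$params[[paste0("up", s, "/W")]]
    Cout <- dim(Wup)[2]
    dup <- bk$dx[, seq_len(Cout), drop = FALSE]
    dskips[[s]] <- bk$dx[, -seq_len(Cout), drop = FALSE]
    ub <- nn_upconv_bwd(upc$x, upc$dims_lo, upc$f, Wup, dup)
    grads[[paste0("up", s, "/W")]] <- ub$dW
    dx <- ub$dx
  }
  p <- sub_params(model$params, "bot")
  bk <- csr_backward(dx, dims_at[["bot"]], p, caches[["bot"]], model$ksz)
  for (k in names(bk$grads)) grads[[paste("bot", k, sep = "/")]] <- bk$grads[[k]]
  dx <- bk$dx
  for (s in rev(seq_len(cfg$depth))) {
    pc <- caches[[paste0("pool", s)]]
    dpool <- nn_maxpool_bwd(pc$pl, pc$dims, pc$C, dx)
    dy <- dpool + dskips[[s]]
    p <- sub_params(model$params, paste0("enc", s))
    bk <- csr_backward(dy, dims_at[[paste0("enc", s)]], p,
                       caches[[paste0("enc", s)]], model$ksz)
    for (k in names(bk$grads)) grads[[paste(paste0("enc", s), k, sep = "/")]] <- bk$grads[[k]]
    dx <- bk$dx
  }
  grads
}

# input adapter: volume array (3D net) or slab (2.5D net) -> matrix + dims
fm_from_input <- function(model, input) {
  v <- if (is_volume_grid(input)) input$values else input
  d <- dim(v)
  if (model$config$dims == "3D") {
    stopifnot(length(d) == 3L)
    list(x = matrix(as.numeric(v), prod(d), 1L), dims = d)
  } else {
    stopifnot(length(d) == 3L, d[3] == model$config$in_channels)
    list(x = matrix(as.numeric(v), d[1] * d[2], d[3]),
         dims = c(d[1], d[2], 1L))
  }
}

#' Forward a volume or slab through a CSR-UNet
#'
#' @param model a `csr_unet`.
#' @param input for 3D models, a 3D array or [volume_grid()]; for 2.5D
#'   models, an (nx x ny x k) slab whose k slices are the input channels.
#' @param train logical; training mode uses batch statistics in the
#'   normalization layers.
#' @return list with `prob` (foreground-probability array: 3D for 3D
#'   models, 2D center-slice for 2.5D), `logits` and `fw` (cache for the
#'   backward pass).
#' @export
unet_apply <- function(model, input, train = FALSE) {
  ad <- fm_from_input(model, input)
  fw <- unet_forward(model, ad$x, ad$dims, train = train)
  probs <- nn_softmax(fw$logits)
  pd <- if (model$config$dims == "3D") ad$dims else ad$dims[1:2]
  list(prob = array(probs[, 2], dim = pd), probs = probs,
       logits = fw$logits, fw = fw, dims = ad$dims)
}

#' Save / load a model checkpoint
#'
#' Stores the configuration, weights and normalization statistics.
#'
#' @param model a `csr_unet`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored `csr_unet` (load).
#' @export
save_checkpoint <- function(model, path) {
  bn <- lapply(as.list(model$bn), as.list)
  saveRDS(list(config = model$config, params = model$params, bn = bn,
               ksz = model$ksz), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  bn <- new.env(parent = emptyenv())
  for (nm in names(obj$bn)) {
    e <- new.env(parent = emptyenv())
    for (k in names(obj$bn[[nm]])) e[[k]] <- obj$bn[[nm]][[k]]
    bn[[nm]] <- e
  }
  structure(list(config = obj$config, params = obj$params, ksz = obj$ksz,
                 bn = bn), class = "csr_unet")
}
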