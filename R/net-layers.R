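# Low-level 3D layer machinery for the DenseNet brain-age regressor.
#
# Feature maps are stored as dense matrices of shape (batch * n_voxels) x channels,
# sample-major (rows 1..n_voxels belong to sample 1). Convolutions are computed by
# an im2col gather followed by one BLAS matrix product; the gather index vectors
# depend only on (spatial dims, kernel, stride, padding, batch size) and are cached
# per layer so they are built once and reused across batches and epochs.

# Geometry of a 3D convolution: output dims, padded-volume size, linear indices of
# the un-padded interior, and the patch index matrix (n_out_voxels x K^3) into the
# padded volume.
conv_geometry <- function(dims, kernel, stride, pad) {
  stopifnot(length(dims) == 3L, kernel >= 1L, stride >= 1L, pad >= 0L)
  dims_out <- (dims + 2L * pad - kernel) %/% stride + 1L
  if (any(dims_out < 1L)) {
    stop("kernel ", kernel, " does not fit input dims [", paste(dims, collapse = "x"),
         "] with pad ", pad, call. = FALSE)
  }
  pd <- dims + 2L * pad
  ax <- function(i) (pad + 1L):(pad + dims[i])
  interior <- as.vector(outer(outer(ax(1), (ax(2) - 1L) * pd[1], "+"),
                              (ax(3) - 1L) * pd[1] * pd[2], "+"))
  kk <- 0:(kernel - 1L)
  koff <- as.vector(outer(outer(kk, kk * pd[1], "+"), kk * pd[1] * pd[2], "+"))
  st <- function(i) seq(0L, by = stride, length.out = dims_out[i])
  base <- as.vector(outer(outer(st(1), st(2) * pd[1], "+"),
                          st(3) * pd[1] * pd[2], "+")) + 1L
  list(dims_out = dims_out, npad = prod(pd), nvox_out = length(base),
       interior = interior, patch = outer(base, koff, "+"), k3 = kernel^3L)
}

# Batched gather/scatter indices. `gather` has length nvox_out*B*K^3 ordered so
# that matrix(Xp[gather, ], nrow = nvox_out * B) yields columns (k fast, channel
# slow) matching the weight layout. `interior` maps the un-padded batch rows into
# the padded batch matrix.
conv_batch_indices <- function(geom, batch, n_vox_in) {
  off_out <- rep((0:(batch - 1L)) * geom$npad, each = geom$nvox_out)
  idx <- matrix(0L, geom$nvox_out * batch, geom$k3)
  for (k in seq_len(geom$k3)) idx[, k] <- rep(geom$patch[, k], batch) + off_out
  interior_rows <- rep(geom$interior, batch) +
    rep((0:(batch - 1L)) * geom$npad, each = n_vox_in)
  list(gather = as.vector(idx), interior_rows = interior_rows)
}

# Per-layer plan cache: plans are keyed by input dims and batch size.
conv_plan <- function(layer, dims, batch) {
  key <- paste(c(dims, batch), collapse = "x")
  plan <- layer$plans[[key]]
  if (is.null(plan)) {
    geom <- conv_geometry(dims, layer$kernel, layer$stride, layer$pad)
    plan <- c(geom, conv_batch_indices(geom, batch, prod(dims)))
    layer$plans[[key]] <- plan
  }
  plan
}

im2col <- function(x, plan, batch) {
  nv <- plan$nvox_out * batch
  if (ncol(x) == 1L) {
    xp <- numeric(batch * plan$npad)
    xp[plan$interior_rows] <- x
    g <- xp[plan$gather]
    dim(g) <- c(nv, plan$k3)
  } else {
    xp <- matrix(0, batch * plan$npad, ncol(x))
    xp[plan$interior_rows, ] <- x
    g <- xp[plan$gather, , drop = FALSE]
    dim(g) <- c(nv, plan$k3 * ncol(x))
  }
  g
}

# Adjoint of im2col. For a fixed kernel offset the output-voxel -> input-voxel
# map is injective, so the scatter-add decomposes into k^3 plain vectorized
# additions with no duplicate-index bookkeeping.
col2im <- function(dcol, plan, batch, n_channels, n_vox_in) {
  k3 <- plan$k3
  nv <- plan$nvox_out * batch
  dxp <- matrix(0, batch * plan$npad, n_channels)
  for (k in seq_len(k3)) {
    rows <- plan$gather[((k - 1L) * nv + 1L):(k * nv)]
    cols <- (seq_len(n_channels) - 1L) * k3 + k
    dxp[rows, ] <- dxp[rows, ] + dcol[, cols, drop = FALSE]
  }
  dxp[plan$interior_rows, , drop = FALSE]
}

conv3d_layer <- function(in_ch, out_ch, kernel, stride = 1L, bias = TRUE,
                         pad = (kernel - 1L) %/% 2L) {
  structure(list(type = "conv", in_ch = in_ch, out_ch = out_ch,
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad), bias = bias,
                 W = matrix(0, kernel^3L * in_ch, out_ch),
                 b = if (bias) numeric(out_ch) else NULL,
                 plans = new.env(parent = emptyenv())),
            class = "brainage_layer")
}

conv_forward <- function(layer, x, dims, batch) {
  if (layer$kernel == 1L && layer$stride == 1L) {
    # pointwise convolution: im2col is the identity
    y <- x %*% layer$W
    if (!is.null(layer$b)) y <- y + rep(layer$b, each = nrow(y))
    return(list(out = y, dims = dims,
                cache = list(xcol = x, plan = NULL, dims_in = dims,
                             batch = batch)))
  }
  plan <- conv_plan(layer, dims, batch)
  xcol <- im2col(x, plan, batch)
  y <- xcol %*% layer$W
  if (!is.null(layer$b)) y <- y + rep(layer$b, each = nrow(y))
  list(out = y, dims = plan$dims_out,
       cache = list(xcol = xcol, plan = plan, dims_in = dims, batch = batch))
}

conv_backward <- function(layer, dy, cache, need_dx = TRUE) {
  dW <- crossprod(cache$xcol, dy)
  db <- if (!is.null(layer$b)) colSums(dy) else NULL
  dx <- NULL
  if (need_dx) {
    dcol <- tcrossprod(dy, layer$W)
    dx <- if (is.null(cache$plan)) dcol else {
      col2im(dcol, cache$plan, cache$batch, layer$in_ch, prod(cache$dims_in))
    }
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

batchnorm_layer <- function(n_ch, eps = 1e-5, momentum = 0.1) {
  structure(list(type = "bn", n_ch = n_ch, eps = eps, momentum = momentum,
                 gamma = rep(1, n_ch), beta = numeric(n_ch),
                 running_mean = numeric(n_ch), running_var = rep(1, n_ch)),
            class = "brainage_layer")
}

bn_forward <- function(layer, x, training) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc * xc)
    inv_sd <- 1 / sqrt(v + layer$eps)
    xhat <- xc * rep(inv_sd, each = n)
    m <- layer$momentum
    layer$running_mean <- (1 - m) * layer$running_mean + m * mu
    layer$running_var <- (1 - m) * layer$running_var + m * v * n / max(n - 1, 1)
    cache <- list(xhat = xhat, inv_sd = inv_sd, training = TRUE)
  } else {
    inv_sd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- (x - rep(layer$running_mean, each = n)) * rep(inv_sd, each = n)
    cache <- list(inv_sd = inv_sd, training = FALSE)
  }
  y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  cache$xhat_for_grad <- if (training) cache$xhat else NULL
  list(out = y, layer = layer, cache = cache)
}

bn_backward <- function(layer, dy, cache) {
  n <- nrow(dy)
  if (cache$training) {
    xhat <- cache$xhat
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dxhat <- dy * rep(layer$gamma, each = n)
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) *
      rep(cache$inv_sd, each = n)
    list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
  } else {
    dx <- dy * rep(layer$gamma * cache$inv_sd, each = n)
    list(dx = dx, grads = NULL)
  }
}

relu_layer <- function() structure(list(type = "relu"), class = "brainage_layer")

avgpool_layer <- function(kernel = 2L, stride = 2L) {
  structure(list(type = "avgpool", kernel = as.integer(kernel),
                 stride = as.integer(stride), pad = 0L,
                 plans = new.env(parent = emptyenv())),
            class = "brainage_layer")
}

avgpool_forward <- function(layer, x, dims, batch) {
  plan <- conv_plan(layer, dims, batch)
  n_ch <- ncol(x)
  xcol <- im2col(x, plan, batch)
  k3 <- plan$k3
  y <- matrix(0, nrow(xcol), n_ch)
  for (c in seq_len(n_ch)) {
    y[, c] <- rowMeans(xcol[, (c - 1L) * k3 + seq_len(k3), drop = FALSE])
  }
  list(out = y, dims = plan$dims_out,
       cache = list(plan = plan, dims_in = dims, batch = batch, n_ch = n_ch))
}

avgpool_backward <- function(layer, dy, cache) {
  k3 <- cache$plan$k3
  dcol <- matrix(0, nrow(dy), k3 * cache$n_ch)
  for (c in seq_len(cache$n_ch)) {
    dcol[, (c - 1L) * k3 + seq_len(k3)] <- dy[, c] / k3
  }
  dx <- col2im(dcol, cache$plan, cache$batch, cache$n_ch, prod(cache$dims_in))
  list(dx = dx, grads = NULL)
}

gap_layer <- function() structure(list(type = "gap"), class = "brainage_layer")

fc_layer <- function(in_ch, out_ch = 1L) {
  structure(list(type = "fc", in_ch = in_ch, out_ch = out_ch,
                 W = matrix(0, in_ch, out_ch), b = numeric(out_ch)),
            class = "brainage_layer")
}
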