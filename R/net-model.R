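# Model assembly and forward/backward passes for the 3D DenseNet.
#
# A model is a flat list of primitive layers plus an index layout derived from
# its net_config; ReLU activations are implicit in the DenseNet wiring (after
# every normalization and after the final convolution).

model_layout <- function(config) {
  idx <- 0L
  nxt <- function() { idx <<- idx + 1L; idx }
  stem <- nxt()
  stem_pool <- if (config$stem_pool) nxt() else NA_integer_
  blocks <- list(); transitions <- list()
  for (b in seq_along(config$block_layers)) {
    blk <- list()
    for (l in seq_len(config$block_layers[b])) {
      blk[[l]] <- c(bn1 = nxt(), conv1 = nxt(), bn2 = nxt(), conv3 = nxt())
    }
    blocks[[b]] <- blk
    if (b < length(config$block_layers)) {
      transitions[[b]] <- c(bn = nxt(), conv = nxt(), pool = nxt())
    }
  }
  final_norm <- if (config$pre_final_norm) nxt() else NA_integer_
  final_conv <- nxt()
  head <- nxt()
  list(stem = stem, stem_pool = stem_pool, blocks = blocks,
       transitions = transitions, final_norm = final_norm,
       final_conv = final_conv, head = head, n = idx)
}

he_init <- function(layer, rng_sd_scale = 1) {
  if (layer$type == "conv") {
    fan_in <- nrow(layer$W)
    layer$W[] <- stats::rnorm(length(layer$W), sd = sqrt(2 / fan_in) * rng_sd_scale)
  } else if (layer$type == "fc") {
    layer$W[] <- stats::rnorm(length(layer$W), sd = sqrt(1 / layer$in_ch) * rng_sd_scale)
  }
  layer
}

#' Build a 3D DenseNet brain-age model
#'
#' Instantiates the network described by a [net_config()]: a stem convolution,
#' dense blocks whose layers each run normalization -> ReLU -> 1x1x1
#' bottleneck -> normalization -> ReLU -> 3x3x3 growth convolution and
#' concatenate `growth_rate` channels onto the block's running feature map,
#' transition blocks (normalization -> 1x1x1 compression -> 2x2x2 average
#' pooling), a final 3x3x3 convolution, global average pooling, and a fully
#' connected scalar head.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @param init Either "he" (random He-normal initialization) or "zero"
#'   (weights untouched; useful for pure bookkeeping such as parameter
#'   counting).
#' @return An object of class `brainage_model`.
#' @export
build_model <- function(config, seed = 42L, init = c("he", "zero")) {
  stopifnot(inherits(config, "net_config"))
  init <- match.arg(init)
  lay <- model_layout(config)
  layers <- vector("list", lay$n)
  s <- config$bottleneck_scale; k <- config$growth_rate
  layers[[lay$stem]] <- conv3d_layer(1L, config$stem_width, config$stem_kernel,
                                     stride = config$stem_stride,
                                     bias = config$bias_stem)
  if (!is.na(lay$stem_pool)) layers[[lay$stem_pool]] <- avgpool_layer(2L, 2L)
  c <- config$stem_width
  for (b in seq_along(config$block_layers)) {
    for (l in seq_len(config$block_layers[b])) {
      ids <- lay$blocks[[b]][[l]]
      sc <- s * c
      layers[[ids["bn1"]]] <- batchnorm_layer(c)
      layers[[ids["conv1"]]] <- conv3d_layer(c, sc, 1L, bias = config$bias_bottleneck)
      layers[[ids["bn2"]]] <- batchnorm_layer(sc)
      layers[[ids["conv3"]]] <- conv3d_layer(sc, k, 3L, bias = config$bias_growth)
      c <- c + k
    }
    if (b < length(config$block_layers)) {
      ids <- lay$transitions[[b]]
      cout <- as.integer(floor(config$compression * c))
      if (cout < 1L) stop("transition ", b, " compresses to < 1 channel")
      layers[[ids["bn"]]] <- batchnorm_layer(c)
      layers[[ids["conv"]]] <- conv3d_layer(c, cout, 1L, bias = config$bias_bottleneck)
      layers[[ids["pool"]]] <- avgpool_layer(2L, 2L)
      c <- cout
    }
  }
  if (!is.na(lay$final_norm)) layers[[lay$final_norm]] <- batchnorm_layer(c)
  layers[[lay$final_conv]] <- conv3d_layer(c, config$final_conv_width, 3L,
                                           bias = config$bias_final)
  layers[[lay$head]] <- fc_layer(config$final_conv_width, 1L)
  if (init == "he") {
    set.seed(seed)
    layers <- lapply(layers, he_init)
  }
  structure(list(config = config, layout = lay, layers = layers),
            class = "brainage_model")
}

#' Trainable-parameter count of an instantiated model
#'
#' Sums the element counts of every trainable tensor (convolution weights and
#' biases, normalization affine pairs, fully connected weights and bias).
#' Serves as the instantiation-side cross-check of [count_parameters()].
#'
#' @param model A [build_model()] result.
#' @return Integer-valued numeric count.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$layers, function(l) {
    switch(l$type,
           conv = length(l$W) + if (is.null(l$b)) 0L else length(l$b),
           fc = length(l$W) + length(l$b),
           bn = 2L * l$n_ch,
           0L)
  }, numeric(1)))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

# Forward pass. `x` is a (batch * n_voxels) x 1 matrix, sample-major; `dims`
# the spatial grid. Returns predictions, per-layer caches for the backward
# pass, and the (possibly updated, via normalization running statistics)
# model.
net_forward <- function(model, x, dims, batch, training = FALSE) {
  lay <- model$layout; L <- model$layers
  caches <- vector("list", lay$n)
  relus <- list()
  cf <- conv_forward(L[[lay$stem]], x, dims, batch)
  caches[[lay$stem]] <- cf$cache
  f <- cf$out; d <- cf$dims
  if (!is.na(lay$stem_pool)) {
    sp <- avgpool_forward(L[[lay$stem_pool]], f, d, batch)
    caches[[lay$stem_pool]] <- sp$cache
    f <- sp$out; d <- sp$dims
  }
  for (b in seq_along(lay$blocks)) {
    for (l in seq_along(lay$blocks[[b]])) {
      ids <- lay$blocks[[b]][[l]]
      bn1 <- bn_forward(L[[ids["bn1"]]], f, training)
      L[[ids["bn1"]]] <- bn1$layer; caches[[ids["bn1"]]] <- bn1$cache
      r1 <- relu_fwd(bn1$out); relus[[paste0("r1_", ids["bn1"])]] <- r1$mask
      c1 <- conv_forward(L[[ids["conv1"]]], r1$out, d, batch)
      caches[[ids["conv1"]]] <- c1$cache
      bn2 <- bn_forward(L[[ids["bn2"]]], c1$out, training)
      L[[ids["bn2"]]] <- bn2$layer; caches[[ids["bn2"]]] <- bn2$cache
      r2 <- relu_fwd(bn2$out); relus[[paste0("r2_", ids["bn2"])]] <- r2$mask
      c3 <- conv_forward(L[[ids["conv3"]]], r2$out, d, batch)
      caches[[ids["conv3"]]] <- c3$cache
      f <- cbind(f, c3$out)
    }
    if (b < length(lay$blocks)) {
      ids <- lay$transitions[[b]]
      bnt <- bn_forward(L[[ids["bn"]]], f, training)
      L[[ids["bn"]]] <- bnt$layer; caches[[ids["bn"]]] <- bnt$cache
      rt <- relu_fwd(bnt$out); relus[[paste0("rt_", ids["bn"])]] <- rt$mask
      ct <- conv_forward(L[[ids["conv"]]], rt$out, d, batch)
      caches[[ids["conv"]]] <- ct$cache
      pt <- avgpool_forward(L[[ids["pool"]]], ct$out, d, batch)
      caches[[ids["pool"]]] <- pt$cache
      f <- pt$out; d <- pt$dims
    }
  }
  if (!is.na(lay$final_norm)) {
    bnf <- bn_forward(L[[lay$final_norm]], f, training)
    L[[lay$final_norm]] <- bnf$layer; caches[[lay$final_norm]] <- bnf$cache
    rf <- relu_fwd(bnf$out); relus[["r_final_norm"]] <- rf$mask
    f <- rf$out
  }
  cf2 <- conv_forward(L[[lay$final_conv]], f, d, batch)
  caches[[lay$final_conv]] <- cf2$cache
  rfc <- relu_fwd(cf2$out); relus[["r_final_conv"]] <- rfc$mask
  nvox <- prod(cf2$dims)
  pooled <- rowsum(rfc$out, group = rep(seq_len(batch), each = nvox)) / nvox
  head <- L[[lay$head]]
  pred <- drop(pooled %*% head$W) + head$b
  model$layers <- L
  list(pred = pred, model = model,
       state = list(caches = caches, relus = relus, pooled = pooled,
                    final_dims = cf2$dims, batch = batch))
}

# Backward pass from d(loss)/d(pred). Returns per-layer gradient list and,
# when `input_grad` is TRUE (saliency), the gradient with respect to the
# input volume(s).
net_backward <- function(model, state, dpred, input_grad = FALSE) {
  lay <- model$layout; L <- model$layers
  caches <- state$caches; relus <- state$relus
  grads <- vector("list", lay$n)
  batch <- state$batch
  head <- L[[lay$head]]
  dpred <- matrix(dpred, ncol = 1L)
  grads[[lay$head]] <- list(W = crossprod(state$pooled, dpred),
                            b = sum(dpred))
  dpooled <- dpred %*% t(head$W)
  nvox <- prod(state$final_dims)
  dconv_out <- dpooled[rep(seq_len(batch), each = nvox), , drop = FALSE] / nvox
  dconv_out <- dconv_out * relus[["r_final_conv"]]
  bw <- conv_backward(L[[lay$final_conv]], dconv_out, caches[[lay$final_conv]])
  grads[[lay$final_conv]] <- bw$grads
  df <- bw$dx
  if (!is.na(lay$final_norm)) {
    df <- df * relus[["r_final_norm"]]
    bwn <- bn_backward(L[[lay$final_norm]], df, caches[[lay$final_norm]])
    grads[[lay$final_norm]] <- bwn$grads
    df <- bwn$dx
  }
  for (b in rev(seq_along(lay$blocks))) {
    if (b < length(lay$blocks)) {
      ids <- lay$transitions[[b]]
      bp <- avgpool_backward(L[[ids["pool"]]], df, caches[[ids["pool"]]])
      bc <- conv_backward(L[[ids["conv"]]], bp$dx, caches[[ids["conv"]]])
      grads[[ids["conv"]]] <- bc$grads
      dr <- bc$dx * relus[[paste0("rt_", ids["bn"])]]
      bbn <- bn_backward(L[[ids["bn"]]], dr, caches[[ids["bn"]]])
      grads[[ids["bn"]]] <- bbn$grads
      df <- bbn$dx
    }
    k <- model$config$growth_rate
    for (l in rev(seq_along(lay$blocks[[b]]))) {
      ids <- lay$blocks[[b]][[l]]
      nc <- ncol(df)
      dh <- df[, (nc - k + 1L):nc, drop = FALSE]
      df <- df[, seq_len(nc - k), drop = FALSE]
      b3 <- conv_backward(L[[ids["conv3"]]], dh, caches[[ids["conv3"]]])
      grads[[ids["conv3"]]] <- b3$grads
      dr2 <- b3$dx * relus[[paste0("r2_", ids["bn2"])]]
      bb2 <- bn_backward(L[[ids["bn2"]]], dr2, caches[[ids["bn2"]]])
      grads[[ids["bn2"]]] <- bb2$grads
      b1 <- conv_backward(L[[ids["conv1"]]], bb2$dx, caches[[ids["conv1"]]])
      grads[[ids["conv1"]]] <- b1$grads
      dr1 <- b1$dx * relus[[paste0("r1_", ids["bn1"])]]
      bb1 <- bn_backward(L[[ids["bn1"]]], dr1, caches[[ids["bn1"]]])
      grads[[ids["bn1"]]] <- bb1$grads
      df <- df + bb1$dx
    }
  }
  if (!is.na(lay$stem_pool)) {
    df <- avgpool_backward(L[[lay$stem_pool]], df, caches[[lay$stem_pool]])$dx
  }
  bs <- conv_backward(L[[lay$stem]], df, caches[[lay$stem]],
                      need_dx = input_grad)
  grads[[lay$stem]] <- bs$grads
  list(grads = grads, dx = bs$dx)
}

#' Predict brain age for a set of volumes
#'
#' Runs the model in evaluation mode (normalization layers use their running
#' statistics, so predictions are independent of batch composition and order).
#'
#' @param model A trained [build_model()] object.
#' @param volumes Matrix with one flattened volume per row, or a single 3D
#'   array.
#' @param dims Spatial dimensions of each volume.
#' @param batch_size Evaluation batch size (does not affect values).
#' @return Numeric vector of predicted brain ages, in years.
#' @export
predict_brain_age <- function(model, volumes, dims, batch_size = 8L) {
  if (is.array(volumes) && length(dim(volumes)) == 3L) {
    volumes <- matrix(as.vector(volumes), nrow = 1L)
  }
  stopifnot(ncol(volumes) == prod(dims))
  n <- nrow(volumes)
  preds <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    idx <- i:j
    x <- matrix(as.vector(t(volumes[idx, , drop = FALSE])), ncol = 1L)
    fw <- net_forward(model, x, dims, length(idx), training = FALSE)
    preds[idx] <- fw$pred
    i <- j + 1L
  }
  preds
}
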