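#' Architecture configuration for the 3D DenseNet brain-age regressor
#'
#' The network is a 3D DenseNet: a stem convolution (default 5x5x5 kernel)
#' followed by four dense blocks separated by transition blocks, a final 3x3x3
#' convolution, global average pooling, and a fully connected layer that
#' predicts a single scalar (brain age, in years). Within each dense layer, a
#' 1x1x1 bottleneck convolution scales the current in-channel dimension `c` to
#' `bottleneck_scale * c` channels before the 3x3x3 growth convolution appends
#' `growth_rate` channels to the block's running feature map.
#'
#' @param stem_width Channels produced by the stem convolution (C0).
#' @param growth_rate Channels appended by each dense layer (k).
#' @param bottleneck_scale Integer multiplier s: the 1x1x1 convolution maps c
#'   in-channels to `s * c` out-channels.
#' @param block_layers Integer vector of dense-layer counts per block.
#' @param compression Fraction of channels retained by each transition block
#'   (applied as `floor(compression * c)`).
#' @param final_conv_width Channels of the 3x3x3 convolution after the last
#'   dense block.
#' @param stem_kernel Stem kernel size per axis.
#' @param stem_stride Stem stride (does not affect the parameter count; small
#'   desk-scale models use 2 to shrink feature maps early).
#' @param stem_pool Apply a parameter-free 2x2x2 average pooling after the
#'   stem convolution. Does not affect the parameter count.
#' @param bias_stem,bias_bottleneck,bias_growth,bias_final Logical toggles for
#'   convolution biases. The default convention places biases only on the stem
#'   and final convolutions, i.e. the convolutions not immediately followed by
#'   a normalization layer.
#' @param pre_final_norm Insert a normalization/ReLU pair between the last
#'   dense block and the final convolution.
#'
#' @return An object of class `net_config`.
#' @seealso [count_parameters()], [build_model()], [reference_net_config()]
#' @export
net_config <- function(stem_width = 120L, growth_rate = 56L,
                       bottleneck_scale = 2L, block_layers = c(3L, 6L, 12L, 8L),
                       compression = 0.5, final_conv_width = 7848L,
                       stem_kernel = 5L, stem_stride = 1L, stem_pool = FALSE,
                       bias_stem = TRUE, bias_bottleneck = FALSE,
                       bias_growth = FALSE, bias_final = TRUE,
                       pre_final_norm = FALSE) {
  cfg <- list(stem_width = as.integer(stem_width),
              growth_rate = as.integer(growth_rate),
              bottleneck_scale = as.integer(bottleneck_scale),
              block_layers = as.integer(block_layers),
              compression = compression,
              final_conv_width = as.integer(final_conv_width),
              stem_kernel = as.integer(stem_kernel),
              stem_stride = as.integer(stem_stride),
              stem_pool = isTRUE(stem_pool),
              bias_stem = bias_stem, bias_bottleneck = bias_bottleneck,
              bias_growth = bias_growth, bias_final = bias_final,
              pre_final_norm = pre_final_norm)
  if (cfg$stem_width < 1L) stop("stem_width must be >= 1")
  if (cfg$growth_rate < 1L) stop("growth_rate must be >= 1")
  if (cfg$bottleneck_scale < 1L) stop("bottleneck_scale must be >= 1")
  if (any(cfg$block_layers < 0L)) stop("block_layers must be non-negative")
  if (cfg$compression <= 0 || cfg$compression > 1) {
    stop("compression must be in (0, 1]")
  }
  if (cfg$final_conv_width < 1L) stop("final_conv_width must be >= 1")
  tr <- channel_trace(cfg)
  bad <- which(tr$widths < 1L)
  if (length(bad)) {
    stop("derived channel width < 1 at ", tr$names[bad[1]], call. = FALSE)
  }
  class(cfg) <- "net_config"
  cfg
}

# Channel bookkeeping through the network: the running in-channel count at
# block entry, after each block, and after each transition.
channel_trace <- function(config) {
  widths <- integer(0); names <- character(0)
  c <- config$stem_width
  widths <- c(widths, c); names <- c(names, "stem")
  for (b in seq_along(config$block_layers)) {
    c <- c + config$block_layers[b] * config$growth_rate
    widths <- c(widths, c); names <- c(names, paste0("block", b))
    if (b < length(config$block_layers)) {
      c <- as.integer(floor(config$compression * c))
      widths <- c(widths, c); names <- c(names, paste0("transition", b))
    }
  }
  list(widths = widths, names = names, final_in = c)
}

#' Closed-form trainable-parameter count
#'
#' Counts every trainable tensor of the architecture described by `config`:
#' convolution weights (and biases where enabled), normalization affine pairs
#' (2 parameters per channel), and the fully connected head. The count is
#' independent of the input grid size because the head is a global average
#' pooling followed by one linear unit.
#'
#' @param config A [net_config()].
#' @return Integer-valued numeric: the total number of trainable parameters.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "net_config"))
  k <- config$growth_rate; s <- config$bottleneck_scale
  total <- config$stem_kernel^3 * config$stem_width +
    if (config$bias_stem) config$stem_width else 0
  c <- config$stem_width
  for (b in seq_along(config$block_layers)) {
    for (l in seq_len(config$block_layers[b])) {
      sc <- s * c
      total <- total + 2 * c                               # norm on block input
      total <- total + c * sc + if (config$bias_bottleneck) sc else 0
      total <- total + 2 * sc                              # norm after bottleneck
      total <- total + 27 * sc * k + if (config$bias_growth) k else 0
      c <- c + k
    }
    if (b < length(config$block_layers)) {
      cout <- floor(config$compression * c)
      total <- total + 2 * c
      total <- total + c * cout + if (config$bias_bottleneck) cout else 0
      c <- cout
    }
  }
  if (config$pre_final_norm) total <- total + 2 * c
  w <- config$final_conv_width
  total <- total + 27 * c * w + if (config$bias_final) w else 0
  total <- total + w + 1                                   # fully connected head
  total
}

#' Resolve a reference configuration against a target parameter count
#'
#' Enumerates a finite grid of candidate configurations with the closed-form
#' counter ([count_parameters()]) and returns those whose count equals
#' `target`. When no candidate matches, the nearest candidates and their
#' counts are reported so the grid can be widened.
#'
#' @param grid A list of [net_config()] objects.
#' @param target Target parameter count (default: the packaged full-scale
#'   reference total, 251,098,737).
#' @param n_nearest How many near-miss candidates to report when no exact
#'   match exists.
#' @return A list with elements `matches` (list of matching configs, possibly
#'   empty) and `nearest` (data frame of candidate counts sorted by distance
#'   to `target`).
#' @export
resolve_reference_config <- function(grid, target = 251098737L, n_nearest = 5L) {
  counts <- vapply(grid, count_parameters, numeric(1))
  hit <- which(counts == target)
  ord <- order(abs(counts - target))
  nearest <- data.frame(candidate = ord[seq_len(min(n_nearest, length(ord)))],
                        count = counts[ord[seq_len(min(n_nearest, length(ord)))]])
  nearest$gap <- nearest$count - target
  list(matches = grid[hit], nearest = nearest, counts = counts)
}

#' The packaged full-scale reference configuration
#'
#' Reads the frozen reference architecture shipped in
#' `inst/extdata/reference_config.yaml`. This configuration was resolved once
#' by a grid search over (stem width, growth rate, bottleneck scale,
#' compression, final convolution width, bias toggles) for the configuration
#' whose closed-form parameter count equals 251,098,737.
#'
#' @return A [net_config()].
#' @export
reference_net_config <- function() {
  path <- system.file("extdata", "reference_config.yaml", package = "brainage")
  y <- yaml::read_yaml(path)
  net_config(stem_width = y$stem_width, growth_rate = y$growth_rate,
             bottleneck_scale = y$bottleneck_scale,
             block_layers = unlist(y$block_layers),
             compression = y$compression,
             final_conv_width = y$final_conv_width,
             stem_kernel = y$stem_kernel, stem_stride = y$stem_stride,
             stem_pool = y$stem_pool,
             bias_stem = y$bias_stem, bias_bottleneck = y$bias_bottleneck,
             bias_growth = y$bias_growth, bias_final = y$bias_final,
             pre_final_norm = y$pre_final_norm)
}

#' Training protocol configuration
#'
#' Defaults mirror the staged protocol used for the full-scale model: five
#' cycles of 15 epochs, mini-batches of 8, mean-absolute-error loss in years,
#' Adam with initial learning rate 5e-6, learning-rate decay by 0.7 at a cycle
#' boundary when the completed cycle produced no new best validation loss,
#' early-stopping patience of 6 epochs, and seed 42.
#'
#' @param cycles Number of training cycles.
#' @param epochs_per_cycle Epochs per cycle.
#' @param batch_size Mini-batch size.
#' @param lr0 Initial learning rate.
#' @param lr_decay Multiplicative learning-rate decay factor.
#' @param patience Early-stopping patience, in epochs without validation
#'   improvement.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param init_head_bias_to_mean Initialize the head bias at the mean training
#'   target so optimization starts from the constant mean-age predictor.
#' @return An object of class `train_config`.
#' @export
train_config <- function(cycles = 5L, epochs_per_cycle = 15L, batch_size = 8L,
                         lr0 = 5e-6, lr_decay = 0.7, patience = 6L, seed = 42L,
                         init_head_bias_to_mean = TRUE) {
  stopifnot(cycles >= 1, epochs_per_cycle >= 1, batch_size >= 1,
            lr0 > 0, lr_decay > 0, patience >= 1)
  structure(list(cycles = as.integer(cycles),
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_decay = lr_decay, patience = as.integer(patience),
                 seed = as.integer(seed),
                 init_head_bias_to_mean = init_head_bias_to_mean),
            class = "train_config")
}
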