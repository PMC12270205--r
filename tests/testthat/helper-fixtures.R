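# Shared desk-scale fixtures.

tiny_net_config <- function(...) {
  args <- utils::modifyList(
    list(stem_width = 4L, growth_rate = 3L, bottleneck_scale = 2L,
         block_layers = c(1L, 1L), compression = 0.5,
         final_conv_width = 5L, stem_kernel = 3L),
    list(...))
  do.call(net_config, args)
}

# Make every weight non-negative and shift normalization offsets positive:
# with positive inputs all pre-activations sit strictly above the ReLU kink,
# so the network is locally linear and central finite differences are exact.
# The backward pass still traverses every layer type.
positive_weight_model <- function(model, shift = 0.5) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type %in% c("conv", "fc")) model$layers[[i]]$W <- abs(l$W)
    if (l$type == "bn") model$layers[[i]]$beta[] <- shift
  }
  model
}

echo_net_config <- function() {
  net_config(stem_width = 8L, growth_rate = 4L, bottleneck_scale = 1L,
             block_layers = c(2L, 2L), compression = 0.5,
             final_conv_width = 16L, stem_kernel = 5L, stem_stride = 2L,
             stem_pool = TRUE)
}

one_subject <- function(group = "CU", ca0 = 70, visits = c(0, 1, 2),
                        saa = NULL) {
  if (is.null(saa)) {
    saa <- if (grepl("LB\\+", group)) "positive" else "negative"
  }
  brainage:::make_subject("S1", group, ca0, "F", 16, "MCI",
                          if (grepl("AD\\+", group)) 30 else 5, 1000,
                          saa, visits)
}

# Low-rank volume-like sample: amplitude/offset variation on two templates
# plus light voxel noise.
lowrank_volumes <- function(n = 60, nv = 1000, seed = 5) {
  set.seed(seed)
  t1 <- stats::rnorm(nv); t2 <- stats::rnorm(nv)
  outer(stats::rnorm(n, 1, 0.2), t1) + outer(stats::rnorm(n, 0, 0.5), t2) +
    matrix(stats::rnorm(n * nv, 0, 0.05), n)
}
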