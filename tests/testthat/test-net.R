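test_that("closed-form parameter count matches a hand-derived small case", {
  # stem 3^3 conv 1->4 with bias: 27*4 + 4 = 112
  # one block, one dense layer (c = 4, s = 2, k = 3):
  #   norm 2*4 = 8; bottleneck 4*8 = 32 (no bias); norm 2*8 = 16;
  #   growth 27*8*3 = 648 (no bias)                       -> 704
  # final conv 3^3, (4+3) -> 5 with bias: 27*7*5 + 5 = 950
  # head: 5 + 1 = 6
  cfg <- net_config(stem_width = 4L, growth_rate = 3L, bottleneck_scale = 2L,
                    block_layers = 1L, compression = 0.5,
                    final_conv_width = 5L, stem_kernel = 3L)
  expect_equal(count_parameters(cfg), 112 + 704 + 950 + 6)
})

test_that("channel bookkeeping matches the dense-block arithmetic", {
  cfg <- net_config(stem_width = 16L, growth_rate = 8L, bottleneck_scale = 2L,
                    block_layers = c(3L, 2L), compression = 0.5,
                    final_conv_width = 10L)
  tr <- brainage:::channel_trace(cfg)
  # channels entering block 2 = compression applied to (C0 + 3k)
  expect_equal(tr$widths[tr$names == "transition1"],
               floor(0.5 * (16 + 3 * 8)))
  expect_equal(tr$final_in, floor(0.5 * (16 + 3 * 8)) + 2 * 8)
})

test_that("closed-form count equals the instantiated count on random configs", {
  set.seed(42)
  for (i in 1:50) {
    cfg <- net_config(stem_width = sample(1:12, 1),
                      growth_rate = sample(1:8, 1),
                      bottleneck_scale = sample(1:3, 1),
                      block_layers = sample(0:3, sample(1:4, 1), replace = TRUE),
                      compression = sample(c(0.5, 0.75, 1), 1),
                      final_conv_width = sample(1:20, 1),
                      stem_kernel = sample(c(3L, 5L), 1),
                      bias_stem = sample(c(TRUE, FALSE), 1),
                      bias_bottleneck = sample(c(TRUE, FALSE), 1),
                      bias_growth = sample(c(TRUE, FALSE), 1),
                      bias_final = sample(c(TRUE, FALSE), 1),
                      pre_final_norm = sample(c(TRUE, FALSE), 1))
    m <- build_model(cfg, init = "zero")
    expect_equal(count_parameters(cfg), model_parameter_count(m))
  }
})

test_that("degenerate architectures still produce one finite scalar", {
  cfg <- net_config(stem_width = 3L, growth_rate = 2L, bottleneck_scale = 1L,
                    block_layers = c(0L, 0L), compression = 0.5,
                    final_conv_width = 4L, stem_kernel = 3L)
  m <- build_model(cfg, seed = 1)
  x <- matrix(stats::rnorm(16^3), ncol = 1)
  fw <- brainage:::net_forward(m, x, c(16L, 16L, 16L), 1L)
  expect_length(fw$pred, 1L)
  expect_true(is.finite(fw$pred))
})

test_that("invalid configurations fail with informative errors", {
  expect_error(net_config(stem_width = 0), "stem_width")
  expect_error(net_config(compression = 0), "compression")
  expect_error(
    net_config(stem_width = 1L, growth_rate = 1L, block_layers = c(0L, 0L),
               compression = 0.5, final_conv_width = 2L),
    "transition1|channel width")
})

test_that("grid resolution returns exact matches and nearest candidates", {
  grid <- list(tiny_net_config(),
               tiny_net_config(stem_width = 6L),
               tiny_net_config(stem_width = 8L))
  counts <- vapply(grid, count_parameters, numeric(1))
  res <- resolve_reference_config(grid, target = counts[2])
  expect_length(res$matches, 1L)
  expect_equal(res$matches[[1]]$stem_width, 6L)

  none <- resolve_reference_config(grid, target = counts[2] + 1)
  expect_length(none$matches, 0L)
  expect_equal(nrow(none$nearest), 3L)
  expect_equal(none$nearest$count[1], counts[2])

  empty <- resolve_reference_config(list(), target = 100)
  expect_length(empty$matches, 0L)
  expect_equal(nrow(empty$nearest), 0L)
})

test_that("the training controller applies patience and cycle-wise decay", {
  tc <- train_config(cycles = 5, epochs_per_cycle = 15, patience = 6,
                     lr0 = 1e-3, lr_decay = 0.7)
  # strictly improving: never stops, never decays
  ctrl <- training_controller(tc)
  dec <- NULL
  for (e in 1:75) dec <- ctrl$record(100 - e)
  expect_false(dec$stop)
  expect_equal(dec$lr, 1e-3)

  # frozen validation loss from epoch e: stops exactly at e + patience
  ctrl <- training_controller(tc)
  e_freeze <- 4L
  stopped_at <- NA
  for (e in 1:30) {
    loss <- if (e <= e_freeze) 10 - e else 10 - e_freeze
    if (ctrl$record(loss)$stop) { stopped_at <- e; break }
  }
  expect_equal(stopped_at, e_freeze + 6L)

  # a full cycle without a new best triggers one decay at the boundary
  tc2 <- train_config(cycles = 3, epochs_per_cycle = 4, patience = 20,
                      lr0 = 1e-3, lr_decay = 0.7)
  ctrl <- training_controller(tc2)
  losses <- c(5, 4, 3, 2,  2, 2, 2, 2,  1.5)
  lr <- vapply(losses, function(l) ctrl$record(l)$lr, numeric(1))
  expect_equal(lr[4], 1e-3)        # cycle 1 improved: no decay
  expect_equal(lr[8], 1e-3 * 0.7)  # cycle 2 flat: decayed at boundary
  expect_equal(lr[9], 1e-3 * 0.7)
})

test_that("training on a toy signal reduces loss and checkpoints the best epoch", {
  set.seed(3)
  dims <- c(16L, 16L, 16L)
  n <- 24
  ages <- stats::runif(n, 30, 90)
  x <- t(vapply(ages, function(a) {
    as.vector(brainage:::render_volume_for_age(a, dims)) +
      stats::rnorm(prod(dims), 0, 0.02)
  }, numeric(prod(dims))))
  cfg <- net_config(stem_width = 4L, growth_rate = 2L, bottleneck_scale = 1L,
                    block_layers = c(1L, 1L), compression = 0.5,
                    final_conv_width = 8L, stem_kernel = 3L, stem_stride = 2L)
  m <- build_model(cfg, seed = 42)
  tc <- train_config(cycles = 1, epochs_per_cycle = 6, batch_size = 8,
                     lr0 = 2e-3, patience = 6, seed = 42)
  st <- staged_train(m, x[1:16, ], ages[1:16], x[17:24, ], ages[17:24],
                     dims, tc)
  expect_equal(st$best_val, min(st$history$val_loss))
  expect_lte(st$best_val, st$history$val_loss[1])
  # checkpointed model reproduces the recorded best validation loss
  mae <- mean(abs(predict_brain_age(st$model, x[17:24, ], dims) -
                    ages[17:24]))
  expect_equal(mae, st$best_val, tolerance = 1e-10)
  expect_error(staged_train(m, x[0, , drop = FALSE], numeric(0),
                            x[17:24, ], ages[17:24], dims, tc), "non-empty")
})

test_that("prediction is deterministic and batch-invariant in evaluation mode", {
  cfg <- tiny_net_config()
  m <- build_model(cfg, seed = 5)
  dims <- c(12L, 12L, 12L)
  set.seed(8)
  x <- matrix(stats::rnorm(8 * prod(dims)), nrow = 8)
  p1 <- predict_brain_age(m, x, dims, batch_size = 8)
  p2 <- predict_brain_age(m, x, dims, batch_size = 8)
  expect_identical(p1, p2)
  p_single <- vapply(1:8, function(i) {
    predict_brain_age(m, x[i, , drop = FALSE], dims, batch_size = 1)
  }, numeric(1))
  expect_equal(p1, p_single, tolerance = 1e-12)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(4)
  dims <- c(12L, 12L, 12L)
  x <- matrix(stats::rnorm(20 * prod(dims)), nrow = 20)
  y <- stats::runif(20, 40, 80)
  cfg <- tiny_net_config(stem_stride = 2L)
  tc <- train_config(cycles = 1, epochs_per_cycle = 3, batch_size = 4,
                     lr0 = 1e-3, seed = 42)
  st1 <- staged_train(build_model(cfg, seed = 42), x[1:16, ], y[1:16],
                      x[17:20, ], y[17:20], dims, tc)
  st2 <- staged_train(build_model(cfg, seed = 42), x[1:16, ], y[1:16],
                      x[17:20, ], y[17:20], dims, tc)
  expect_identical(st1$history, st2$history)
})
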