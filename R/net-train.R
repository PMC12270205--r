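# Staged training of the brain-age model: Adam on mean-absolute-error loss,
# cycle-wise learning-rate decay, epoch-global early stopping, and
# best-validation checkpointing.

adam_state_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
           conv = list(mW = l$W * 0, vW = l$W * 0,
                       mb = if (is.null(l$b)) NULL else l$b * 0,
                       vb = if (is.null(l$b)) NULL else l$b * 0),
           fc = list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0),
           bn = list(mg = l$gamma * 0, vg = l$gamma * 0,
                     mb = l$beta * 0, vb = l$beta * 0),
           NULL)
  })
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t); vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]; s <- state[[i]]
    if (l$type %in% c("conv", "fc")) {
      u <- upd(l$W, g$W, s$mW, s$vW)
      l$W <- u$p; s$mW <- u$m; s$vW <- u$v
      if (!is.null(l$b) && !is.null(g$b)) {
        u <- upd(l$b, g$b, s$mb, s$vb)
        l$b <- u$p; s$mb <- u$m; s$vb <- u$v
      }
    } else if (l$type == "bn") {
      u <- upd(l$gamma, g$gamma, s$mg, s$vg)
      l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- upd(l$beta, g$beta, s$mb, s$vb)
      l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    }
    layers[[i]] <- l; state[[i]] <- s
  }
  list(layers = layers, state = state)
}

#' Early-stopping and learning-rate schedule controller
#'
#' Encapsulates the staged-training control rules so they can be exercised on
#' synthetic loss traces: training halts once the validation loss has not
#' improved for `patience` consecutive epochs (the counter is epoch-global,
#' resetting only on improvement), and at each cycle boundary the learning
#' rate is multiplied by `lr_decay` if no epoch of the completed cycle set a
#' new best validation loss.
#'
#' @param tc A [train_config()].
#' @return An environment with a `record(val_loss)` function returning a list
#'   with `improved`, `stop`, and `lr` after each epoch.
#' @export
training_controller <- function(tc) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$since_best <- 0L; env$lr <- tc$lr0
  env$epoch <- 0L; env$cycle_improved <- FALSE
  env$record <- function(val_loss) {
    env$epoch <- env$epoch + 1L
    improved <- val_loss < env$best
    if (improved) {
      env$best <- val_loss
      env$since_best <- 0L
      env$cycle_improved <- TRUE
    } else {
      env$since_best <- env$since_best + 1L
    }
    stop_now <- env$since_best >= tc$patience
    end_of_cycle <- env$epoch %% tc$epochs_per_cycle == 0L
    if (end_of_cycle && !stop_now) {
      if (!env$cycle_improved) env$lr <- env$lr * tc$lr_decay
      env$cycle_improved <- FALSE
    }
    list(improved = improved, stop = stop_now, lr = env$lr)
  }
  env
}

mae_loss <- function(pred, y) mean(abs(pred - y))

batch_matrix <- function(volumes, idx) {
  matrix(as.vector(t(volumes[idx, , drop = FALSE])), ncol = 1L)
}

eval_loss <- function(model, volumes, y, dims, batch_size = 8L) {
  mae_loss(predict_brain_age(model, volumes, dims, batch_size), y)
}

#' Staged training of the brain-age regressor
#'
#' Runs up to `cycles * epochs_per_cycle` epochs of Adam on mean-absolute-
#' error loss (years). Validation loss is evaluated after every epoch; the
#' best model state is checkpointed whenever it improves; training early-stops
#' after `patience` consecutive non-improving epochs; the learning rate decays
#' by `lr_decay` at a cycle boundary whose completed cycle produced no new
#' best. Fully seeded: initialization and shuffling derive from `tc$seed`.
#'
#' @param model A [build_model()] result.
#' @param train_x,train_y Training volumes (matrix, one flattened volume per
#'   row) and chronological ages (years).
#' @param val_x,val_y Validation volumes and ages.
#' @param dims Spatial dimensions of each volume.
#' @param tc A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A train-state list: `history` (per-epoch data frame), `best_val`,
#'   `best_epoch`, `stopped_early`, and `model` (the checkpointed best state).
#' @export
staged_train <- function(model, train_x, train_y, val_x, val_y, dims, tc,
                         verbose = FALSE) {
  stopifnot(inherits(tc, "train_config"))
  if (nrow(train_x) == 0L || nrow(val_x) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  stopifnot(nrow(train_x) == length(train_y), nrow(val_x) == length(val_y))
  set.seed(tc$seed)
  if (tc$init_head_bias_to_mean) {
    model$layers[[model$layout$head]]$b <- mean(train_y)
  }
  state <- adam_state_init(model$layers)
  ctrl <- training_controller(tc)
  hist <- list()
  best_model <- model; best_val <- Inf; best_epoch <- 0L
  stopped <- FALSE; t_adam <- 0L
  n <- nrow(train_x)
  for (cycle in seq_len(tc$cycles)) {
    for (ep in seq_len(tc$epochs_per_cycle)) {
      epoch <- (cycle - 1L) * tc$epochs_per_cycle + ep
      ord <- sample.int(n)
      tl <- 0; nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + tc$batch_size - 1L, n)
        idx <- ord[i:j]
        x <- batch_matrix(train_x, idx)
        fw <- net_forward(model, x, dims, length(idx), training = TRUE)
        model <- fw$model
        resid <- fw$pred - train_y[idx]
        loss <- mean(abs(resid))
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; check input scaling and learning rate")
        }
        dpred <- sign(resid) / length(idx)
        bw <- net_backward(model, fw$state, dpred)
        t_adam <- t_adam + 1L
        up <- adam_step(model$layers, bw$grads, state, ctrl$lr, t_adam)
        model$layers <- up$layers; state <- up$state
        tl <- tl + loss; nb <- nb + 1L
        i <- j + 1L
      }
      vl <- eval_loss(model, val_x, val_y, dims, tc$batch_size)
      dec <- ctrl$record(vl)
      if (dec$improved) {
        best_model <- model; best_val <- vl; best_epoch <- epoch
      }
      hist[[epoch]] <- data.frame(epoch = epoch, cycle = cycle,
                                  train_loss = tl / nb, val_loss = vl,
                                  lr = dec$lr)
      if (verbose) {
        message(sprintf("epoch %3d  train %.3f  val %.3f  lr %.2e",
                        epoch, tl / nb, vl, dec$lr))
      }
      if (dec$stop) { stopped <- TRUE; break }
    }
    if (stopped) break
  }
  list(history = do.call(rbind, hist), best_val = best_val,
       best_epoch = best_epoch, stopped_early = stopped, model = best_model)
}
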