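# Two-stage training: masked-reconstruction pre-training on unlabeled angle
# windows, then supervised fine-tuning of a partially frozen model on
# angle -> moment windows, plus the from-scratch supervised baseline and the
# nested label-fraction subsampler.

#' Pre-training hyperparameters
#'
#' Defaults mirror the reference protocol: Adam at 1e-4, batch 64, 2000
#' epochs with cosine annealing, weight decay 1e-5, dropout 0.1, mask ratio
#' 0.10, per-epoch shuffling.  Scaled-down runs lower `epochs` (and usually
#' raise `lr`), nothing else.
#'
#' @param lr Initial learning rate (> 0).
#' @param batch_size Windows per optimization step.
#' @param epochs Training epochs (>= 1).
#' @param weight_decay L2 penalty folded into the gradient.
#' @param mask_ratio Masked-patch fraction in (0, 1).
#' @param loss_on `"masked"` (default: reconstruction error on masked
#'   positions only) or `"all"` positions.
#' @param seed Integer seed governing initialization, shuffling, masking and
#'   dropout.
#' @return Object of class `pretrain_spec`.
#' @export
pretrain_spec <- function(lr = 1e-4, batch_size = 64L, epochs = 2000L,
                          weight_decay = 1e-5, mask_ratio = 0.10,
                          loss_on = c("masked", "all"), seed = 1L) {
  loss_on <- match.arg(loss_on)
  if (lr <= 0) stop_invalid("lr must be positive")
  if (epochs < 1) stop_invalid("epochs must be >= 1")
  if (mask_ratio <= 0 || mask_ratio >= 1)
    stop_invalid("pre-training requires a mask ratio in (0, 1): the ",
                 "reconstruction loss is defined on the masked set")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 mask_ratio = mask_ratio, loss_on = loss_on,
                 schedule = "cosine", seed = as.integer(seed)),
            class = "pretrain_spec")
}

#' Fine-tuning hyperparameters
#'
#' Defaults: Adam at 1e-6 (1/100 of the pre-training rate), batch 64, 500
#' epochs, reduce-on-plateau schedule on validation loss (factor 0.5,
#' patience 10), early stopping with patience 20, first 6 of 8 blocks frozen.
#'
#' @param lr Initial learning rate.
#' @param batch_size Windows per step.
#' @param epochs Epoch cap.
#' @param weight_decay L2 penalty.
#' @param n_frozen_blocks Leading encoder blocks excluded from updates.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param plateau_factor,plateau_patience Reduce-on-plateau parameters.
#' @param label_fraction Fraction of training labels to use (see
#'   [subsample_labels()]).
#' @param freeze_embedding Freeze the input projection along with the frozen
#'   blocks.  The default `TRUE` treats the embedding as part of the frozen
#'   prefix; set `FALSE` to let the fresh projection adapt to the frozen
#'   pre-trained blocks (recommended when the channel count changes).
#' @param head_warm_start Initialize the regression head from the
#'   reconstruction readout of each target's corresponding angle channel,
#'   followed by a closed-form per-channel affine calibration to the
#'   training moments (default `TRUE`).
#' @param seed Integer seed.
#' @return Object of class `finetune_spec`.
#' @export
finetune_spec <- function(lr = 1e-6, batch_size = 64L, epochs = 500L,
                          weight_decay = 1e-5, n_frozen_blocks = 6L,
                          early_stopping_patience = 20L,
                          plateau_factor = 0.5, plateau_patience = 10L,
                          label_fraction = 1, freeze_embedding = TRUE,
                          head_warm_start = TRUE, seed = 1L) {
  if (lr <= 0) stop_invalid("lr must be positive")
  if (early_stopping_patience < 1) stop_invalid("patience must be >= 1")
  if (label_fraction <= 0 || label_fraction > 1)
    stop_invalid("label_fraction must be in (0, 1]")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 n_frozen_blocks = as.integer(n_frozen_blocks),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 label_fraction = label_fraction,
                 freeze_embedding = isTRUE(freeze_embedding),
                 head_warm_start = isTRUE(head_warm_start),
                 schedule = "plateau", seed = as.integer(seed)),
            class = "finetune_spec")
}

# ---------------------------------------------------------------------------
# optimizer

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, weight_decay, frozen,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, epoch, total) {
  0.5 * lr0 * (1 + cos(pi * (epoch - 1) / max(1, total)))
}

# ---------------------------------------------------------------------------
# training engine

# ws -> patch-level matrices; rows of window i occupy a contiguous block
ws_to_matrices <- function(ws, spec) {
  n <- n_windows(ws)
  if (spec$patch_length == 1L) {
    X <- batch_to_matrix(ws$inputs)
    Tm <- if (!is.null(ws$targets)) batch_to_matrix(ws$targets)
  } else {
    X <- do.call(rbind, lapply(seq_len(n), function(i)
      patches_matrix(ws$inputs[i, , ], spec)))
    Tm <- if (!is.null(ws$targets))
      do.call(rbind, lapply(seq_len(n), function(i) {
        sp2 <- spec; sp2$n_channels_in <- spec$n_channels_out
        patches_matrix(ws$targets[i, , ], sp2)
      }))
  }
  list(X = X, T = Tm, n = n)
}

eval_loss <- function(model, X, Tm, W, batch_size = 256L) {
  n <- nrow(X) %/% W
  tot <- 0
  for (b0 in seq(1L, n, by = batch_size)) {
    b1 <- min(n, b0 + batch_size - 1L)
    rows <- ((b0 - 1L) * W + 1L):(b1 * W)
    fwd <- model_forward_pass(model, X[rows, , drop = FALSE], W,
                              training = FALSE)
    tot <- tot + sum((fwd$Y - Tm[rows, , drop = FALSE])^2)
  }
  tot / length(Tm)
}

# mode "masked": reconstruct X at masked token positions; mode "supervised":
# regress Tm at all positions.  Returns best-monitor model and a TrainLog.
train_engine <- function(model, train, val = NULL,
                         mode = c("masked", "supervised"),
                         lr, epochs, batch_size, weight_decay,
                         schedule = c("cosine", "plateau", "constant"),
                         mask_ratio = 0.10, loss_on = "masked",
                         early_stopping_patience = Inf,
                         plateau_factor = 0.5, plateau_patience = 10L,
                         seed = 1L) {
  mode <- match.arg(mode)
  schedule <- match.arg(schedule)
  spec <- model$spec
  W <- n_patches(spec)
  tr <- ws_to_matrices(train, spec)
  if (mode == "supervised" && is.null(tr$T))
    stop_schema("supervised training requires target windows")
  va <- if (!is.null(val)) ws_to_matrices(val, spec)
  opt <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), lr = numeric(0))
  best <- list(monitor = Inf, params = model$params, epoch = 0L)
  cur_lr <- lr
  bad_early <- 0L
  bad_plateau <- 0L
  stop_reason <- "epoch_cap"
  for (epoch in seq_len(epochs)) {
    if (schedule == "cosine") cur_lr <- cosine_lr(lr, epoch, epochs)
    set.seed(substream_seed(seed, "epoch", epoch))
    ord <- sample(tr$n)
    ep_loss <- 0
    ep_n <- 0
    for (b0 in seq(1L, tr$n, by = batch_size)) {
      ids <- ord[b0:min(tr$n, b0 + batch_size - 1L)]
      rows <- as.vector(vapply(ids, function(i) ((i - 1L) * W + 1L):(i * W),
                               integer(W)))
      Xb <- tr$X[rows, , drop = FALSE]
      if (mode == "masked") {
        midx <- draw_batch_mask(length(ids), W, mask_ratio)
        fwd <- model_forward_pass(model, Xb, W, mask_idx = midx,
                                  training = TRUE)
        Tb <- Xb
        if (loss_on == "masked") {
          sel <- midx
        } else sel <- seq_len(nrow(Xb))
        denom <- length(sel) * ncol(fwd$Y)
        R <- fwd$Y[sel, , drop = FALSE] - Tb[sel, , drop = FALSE]
        loss <- sum(R * R) / denom
        dY <- matrix(0, nrow(fwd$Y), ncol(fwd$Y))
        dY[sel, ] <- 2 * R / denom
      } else {
        Tb <- tr$T[rows, , drop = FALSE]
        fwd <- model_forward_pass(model, Xb, W, training = TRUE)
        R <- fwd$Y - Tb
        loss <- mean(R * R)
        dY <- 2 * R / length(R)
      }
      grads <- model_backward_pass(model, fwd, dY)
      upd <- adam_step(model$params, grads, opt, cur_lr, weight_decay,
                       model$frozen)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss * length(ids)
      ep_n <- ep_n + length(ids)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- if (!is.null(va)) eval_loss(model, va$X, va$T, W) else NA_real_
    monitor <- if (!is.null(va)) val_loss else train_loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss, lr = cur_lr))
    if (monitor < best$monitor - 1e-12) {
      best <- list(monitor = monitor, params = model$params, epoch = epoch)
      bad_early <- 0L
      bad_plateau <- 0L
    } else {
      bad_early <- bad_early + 1L
      bad_plateau <- bad_plateau + 1L
      if (schedule == "plateau" && bad_plateau >= plateau_patience) {
        cur_lr <- cur_lr * plateau_factor
        bad_plateau <- 0L
      }
      if (bad_early >= early_stopping_patience) {
        stop_reason <- "early_stopping"
        break
      }
    }
  }
  model$params <- best$params
  list(model = model,
       log = structure(log, class = c("train_log", "data.frame"),
                       stop_reason = stop_reason, best_epoch = best$epoch,
                       best_monitor = best$monitor),
       stop_reason = stop_reason, best_epoch = best$epoch)
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save / load a model checkpoint
#'
#' A checkpoint is a single self-describing archive holding the architecture
#' spec, all weights (including the mask token), the input normalization
#' statistics, and training-stage provenance (stage, epochs, seed, digest).
#'
#' @param model A `gait_model`.
#' @param path File path (`.rds`).
#' @param stats Optional normalization statistics from [standardize()].
#' @param provenance Named list (stage, epochs, seed, ...).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model`, `stats`, `provenance`.
#' @export
save_checkpoint <- function(model, path, stats = NULL, provenance = list()) {
  saveRDS(list(model = model, stats = stats, provenance = provenance,
               format = "gaitssl-checkpoint-v1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "gaitssl-checkpoint-v1"))
    stop_schema("not a gaitssl checkpoint: ", path)
  x
}

# ---------------------------------------------------------------------------
# stages

#' Masked-reconstruction pre-training
#'
#' Trains the auto-encoder to reconstruct the original content of masked
#' patches from the visible context, minimizing MSE over the masked
#' positions (or all positions when `spec$loss_on = "all"`).  The whole
#' window set is used for training; no test split is held out at this stage.
#'
#' @param windows An unlabeled, standardized `window_set` whose channel count
#'   matches `model_spec$n_channels_in`.
#' @param model_spec A [model_spec()].
#' @param spec A [pretrain_spec()].
#' @return List with `model` (a `gait_model` tagged with stage
#'   `"pretrain"`), `log` (TrainLog), `stats` (normalization statistics
#'   carried from `windows`), and `channel_names`.
#' @export
pretrain <- function(windows, model_spec, spec = pretrain_spec()) {
  if (dim(windows$inputs)[3] != model_spec$n_channels_in)
    stop_schema("window set has ", dim(windows$inputs)[3],
                " channels; model expects ", model_spec$n_channels_in)
  if (dim(windows$inputs)[2] != model_spec$window)
    stop_schema("window length mismatch")
  model <- init_model(model_spec, seed = spec$seed)
  res <- train_engine(model, windows, val = NULL, mode = "masked",
                      lr = spec$lr, epochs = spec$epochs,
                      batch_size = spec$batch_size,
                      weight_decay = spec$weight_decay, schedule = "cosine",
                      mask_ratio = spec$mask_ratio, loss_on = spec$loss_on,
                      seed = spec$seed)
  res$model$stage <- "pretrain"
  list(model = res$model, log = res$log, stats = windows$stats,
       channel_names = windows$channel_names)
}

#' Uniformly subsample labeled training windows, nested across fractions
#'
#' A fixed random permutation is drawn once from the seed and the first
#' `round(fraction * n)` entries are kept, so the 5% subset under a given
#' seed is contained in the 20% subset under the same seed.  Apply to the
#' training partition only; validation and test sets stay fixed.
#'
#' @param labeled A labeled `window_set`.
#' @param fraction Label fraction in (0, 1].
#' @param seed Integer seed.
#' @return The subsampled `window_set`.
#' @export
subsample_labels <- function(labeled, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop_invalid("fraction must be in (0, 1]")
  n <- n_windows(labeled)
  k <- round(fraction * n)
  if (k < 1) stop_invalid("fraction ", fraction, " yields zero windows")
  perm <- with_substream(seed, "labels", 0L, sample(n))
  subset_windows(labeled, sort(perm[seq_len(k)]))
}

# build the fine-tuning model from a pre-trained checkpoint: encoder blocks
# are copied; a fresh input projection is made for the (usually smaller)
# channel set, warm-started from the pre-trained rows of matching channels;
# the regression head is fresh.
adapt_checkpoint <- function(ckpt, n_channels_in, n_channels_out,
                             channel_names = NULL, seed = 1L) {
  base <- ckpt$model
  spec <- base$spec
  spec$n_channels_in <- as.integer(n_channels_in)
  spec$n_channels_out <- as.integer(n_channels_out)
  model <- init_model(spec, seed = seed)
  keep <- grep("^(block|mask_token)", names(base$params), value = TRUE)
  model$params[keep] <- base$params[keep]
  pre_ch <- ckpt$channel_names
  if (spec$patch_length == 1L && !is.null(pre_ch) &&
      !is.null(channel_names) && all(channel_names %in% pre_ch)) {
    model$params[["embed.W"]] <-
      base$params[["embed.W"]][match(channel_names, pre_ch), , drop = FALSE]
  } else if (spec$patch_length == 1L) {
    model$params[["embed.W"]] <-
      matrix(colMeans(base$params[["embed.W"]]), n_channels_in,
             spec$d_model, byrow = TRUE)
  }
  model$params[["embed.b"]] <- base$params[["embed.b"]]
  model
}

# initialize the regression head bias at the per-channel mean of the
# training targets so neither arm spends its step budget learning the offset
init_head_bias <- function(model, train) {
  if (model$spec$patch_length == 1L && !is.null(train$targets)) {
    k <- dim(train$targets)[3]
    model$params[["head.b"]] <- vapply(seq_len(k), function(c)
      mean(train$targets[, , c]), numeric(1))
  }
  model
}

# Warm-start the regression head from the reconstruction readout of each
# target's same-joint angle channel, then calibrate each output channel with
# the closed-form least-squares affine map from the warm predictions to the
# training moments.  Falls back to the mean-bias init when the readout
# carries no variance.
warm_start_head <- function(model, ckpt, train) {
  spec <- model$spec
  pre_ch <- ckpt$channel_names
  tnames <- train$target_names
  if (spec$patch_length != 1L || is.null(pre_ch) || is.null(tnames) ||
      !all(tnames %in% names(.moment_angle_channel)))
    return(init_head_bias(model, train))
  ang <- .moment_angle_channel[tnames]
  if (!all(ang %in% pre_ch)) return(init_head_bias(model, train))
  cols <- match(ang, pre_ch)
  model$params[["head.W"]] <- ckpt$model$params[["head.W"]][, cols,
                                                            drop = FALSE]
  model$params[["head.b"]] <- ckpt$model$params[["head.b"]][cols]
  pred <- model_forward(model, train$inputs)
  for (t in seq_along(tnames)) {
    p <- as.vector(pred[, , t])
    y <- as.vector(train$targets[, , t])
    vp <- stats::var(p)
    if (!is.finite(vp) || vp < 1e-10) {
      model$params[["head.W"]][, t] <- 0
      model$params[["head.b"]][t] <- mean(y)
    } else {
      a <- stats::cov(p, y) / vp
      b <- mean(y) - a * mean(p)
      model$params[["head.W"]][, t] <- a * model$params[["head.W"]][, t]
      model$params[["head.b"]][t] <- a * model$params[["head.b"]][t] + b
    }
  }
  model
}

#' Supervised fine-tuning of a pre-trained model
#'
#' Builds a joint-specific model from a pre-trained checkpoint (fresh input
#' projection warm-started from the matching pre-trained channel rows, fresh
#' regression head, encoder blocks copied), freezes the first
#' `n_frozen_blocks` blocks plus the embedding, and trains with supervised
#' MSE on the moment windows.  No masking is applied.  Reduce-on-plateau and
#' early stopping run on the validation loss; the returned model is the one
#' with the best validation loss.
#'
#' @param pretrained Result of [pretrain()] (or a loaded checkpoint list with
#'   `model` and `channel_names`).
#' @param train,val Labeled, standardized `window_set`s (inputs: angle
#'   channels; targets: matching moment channels in N·m/kg).
#' @param spec A [finetune_spec()]; `label_fraction < 1` subsamples the
#'   training windows via [subsample_labels()].
#' @return List with `model`, `log`, `stats`.
#' @export
finetune <- function(pretrained, train, val, spec = finetune_spec()) {
  if (is.null(train$targets)) stop_schema("train windows carry no targets")
  if (!identical(pretrained$model$stage, "pretrain"))
    stop_schema("checkpoint stage must be 'pretrain'")
  if (spec$label_fraction < 1)
    train <- subsample_labels(train, spec$label_fraction, spec$seed)
  model <- adapt_checkpoint(pretrained, dim(train$inputs)[3],
                            dim(train$targets)[3],
                            channel_names = train$channel_names,
                            seed = spec$seed)
  model <- if (isTRUE(spec$head_warm_start))
    warm_start_head(model, pretrained, train)
  else init_head_bias(model, train)
  model <- freeze_prefix(model, spec$n_frozen_blocks,
                         include_embedding = spec$freeze_embedding &&
                           spec$n_frozen_blocks > 0)
  res <- train_engine(model, train, val, mode = "supervised",
                      lr = spec$lr, epochs = spec$epochs,
                      batch_size = spec$batch_size,
                      weight_decay = spec$weight_decay, schedule = "plateau",
                      early_stopping_patience = spec$early_stopping_patience,
                      plateau_factor = spec$plateau_factor,
                      plateau_patience = spec$plateau_patience,
                      seed = spec$seed)
  res$model$stage <- "finetune"
  list(model = res$model, log = res$log, stats = train$stats)
}

#' From-scratch supervised baseline
#'
#' Identical architecture to the fine-tuned model, trained directly on the
#' labeled windows from random initialization with the pre-training
#' optimizer settings (Adam at the pre-training learning rate, cosine
#' annealing).  The best-validation model is returned.
#'
#' @param train,val Labeled `window_set`s as in [finetune()].
#' @param base_spec A [model_spec()] describing the shared architecture
#'   (input/output channel counts are taken from the data).
#' @param spec A [pretrain_spec()]-style supervised configuration (its
#'   `mask_ratio` is ignored).
#' @param label_fraction Optional training-label fraction.
#' @return List with `model`, `log`, `stats`.
#' @export
train_baseline <- function(train, val, base_spec,
                           spec = pretrain_spec(), label_fraction = 1) {
  if (is.null(train$targets)) stop_schema("train windows carry no targets")
  if (label_fraction < 1)
    train <- subsample_labels(train, label_fraction, spec$seed)
  mspec <- base_spec
  mspec$n_channels_in <- dim(train$inputs)[3]
  mspec$n_channels_out <- dim(train$targets)[3]
  model <- init_model(mspec, seed = spec$seed)
  model <- init_head_bias(model, train)
  res <- train_engine(model, train, val, mode = "supervised",
                      lr = spec$lr, epochs = spec$epochs,
                      batch_size = spec$batch_size,
                      weight_decay = spec$weight_decay, schedule = "cosine",
                      seed = spec$seed)
  res$model$stage <- "baseline"
  list(model = res$model, log = res$log, stats = train$stats)
}

#' Predict moment windows for a labeled window set
#'
#' @param model A fine-tuned or baseline `gait_model`.
#' @param windows A `window_set` (standardized like the training data).
#' @return `n` x `window` x `n_channels_out` array of predictions (N·m/kg).
#' @export
predict_moments <- function(model, windows) {
  model_forward(model, windows$inputs)
}

#' Test-set mean squared error of a trained model
#'
#' @param fit Result of [finetune()] or [train_baseline()].
#' @param test A labeled `window_set`.
#' @return Scalar MSE over all predicted moment samples, (N·m/kg)^2.
#' @export
test_mse <- function(fit, test) {
  pred <- predict_moments(fit$model, test)
  mean((pred - test$targets)^2)
}
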