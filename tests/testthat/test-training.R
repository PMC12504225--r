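# Training stages: pre-training progress and determinism, fine-tuning with
# frozen prefixes and early stopping, the from-scratch baseline, and
# checkpointing.

test_that("masked pre-training reduces the reconstruction loss", {
  ds <- toy_dataset(seed = 6, n_subjects = 3, cycles = 2)
  uw <- standardize(windows_from_dataset(ds, 16, 4))
  sp <- toy_model_spec(n_in = 18L)
  for (seed in 1:3) {
    res <- pretrain(uw, sp, pretrain_spec(lr = 1e-3, epochs = 8,
                                          seed = seed))
    expect_lt(tail(res$log$train_loss, 1), res$log$train_loss[1])
    expect_identical(res$model$stage, "pretrain")
  }
})

test_that("pre-training rejects a zero mask ratio and bad channel counts", {
  expect_error(pretrain_spec(mask_ratio = 0),
               class = "gaitssl_invalid_argument")
  ds <- toy_dataset(seed = 6, n_subjects = 2, cycles = 1)
  pair <- joint_pair("knee")
  lab <- windows_from_dataset(ds, 16, 8, channels = pair$angles)
  expect_error(pretrain(lab, toy_model_spec(n_in = 18L), pretrain_spec()),
               class = "gaitssl_schema_error")
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- toy_dataset(seed = 3, n_subjects = 2, cycles = 1)
  uw <- standardize(windows_from_dataset(ds, 16, 8))
  sp <- toy_model_spec(n_in = 18L)
  r1 <- pretrain(uw, sp, pretrain_spec(lr = 1e-3, epochs = 4, seed = 5))
  r2 <- pretrain(uw, sp, pretrain_spec(lr = 1e-3, epochs = 4, seed = 5))
  expect_equal(tail(r1$log$train_loss, 1), tail(r2$log$train_loss, 1),
               tolerance = 1e-6)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("fine-tuning keeps frozen parameters bit-identical", {
  ds <- toy_dataset(seed = 2)
  pt <- toy_pretrained(ds, epochs = 3)
  parts <- toy_labeled(ds)
  fs <- finetune_spec(lr = 1e-3, batch_size = 16, epochs = 4,
                      n_frozen_blocks = 1, early_stopping_patience = 4,
                      seed = 1)
  ft <- finetune(pt, parts$train, parts$val, fs)
  expect_identical(ft$model$params[["block01.Wq"]],
                   pt$model$params[["block01.Wq"]])
  expect_identical(ft$model$params[["block01.W2"]],
                   pt$model$params[["block01.W2"]])
  # unfrozen block and head did move
  expect_false(identical(ft$model$params[["block02.Wq"]],
                         pt$model$params[["block02.Wq"]]))
})

test_that("the 18-to-2 channel transition uses a fresh warm-started input
           projection", {
  ds <- toy_dataset(seed = 2)
  pt <- toy_pretrained(ds, epochs = 3)
  parts <- toy_labeled(ds)
  m <- gaitssl:::adapt_checkpoint(pt, 2L, 2L,
                                  channel_names = parts$train$channel_names,
                                  seed = 1)
  expect_equal(dim(m$params[["embed.W"]]), c(2L, 8L))
  pre <- match(parts$train$channel_names, pt$channel_names)
  expect_equal(m$params[["embed.W"]],
               pt$model$params[["embed.W"]][pre, , drop = FALSE])
  expect_identical(m$params[["block01.Wq"]], pt$model$params[["block01.Wq"]])
})

test_that("constant targets are fit to ~zero error and stop early", {
  ds <- toy_dataset(seed = 9, n_subjects = 3, cycles = 2)
  pt <- toy_pretrained(ds, epochs = 3)
  parts <- toy_labeled(ds, step = 4)
  for (p in c("train", "val")) parts[[p]]$targets[] <- 0.7
  fs <- finetune_spec(lr = 1e-3, batch_size = 32, epochs = 60,
                      n_frozen_blocks = 0, early_stopping_patience = 5,
                      freeze_embedding = FALSE, seed = 1)
  ft <- finetune(pt, parts$train, parts$val, fs)
  expect_lt(min(ft$log$val_loss), 1e-3)
  expect_lt(nrow(ft$log), 60)
  expect_identical(attr(ft$log, "stop_reason"), "early_stopping")
  best <- attr(ft$log, "best_epoch")
  expect_equal(ft$log$val_loss[best], min(ft$log$val_loss))
})

test_that("baseline shares the architecture and learns from scratch", {
  ds <- toy_dataset(seed = 4)
  parts <- toy_labeled(ds)
  sp <- toy_model_spec(n_in = 18L)
  bl <- train_baseline(parts$train, parts$val, sp,
                       pretrain_spec(lr = 1e-3, batch_size = 16,
                                     epochs = 6, seed = 2))
  expect_lt(tail(bl$log$train_loss, 1), bl$log$train_loss[1])
  # architecture parity with the SSL fine-tune model
  pt <- toy_pretrained(ds, epochs = 2)
  ft <- finetune(pt, parts$train, parts$val,
                 finetune_spec(lr = 1e-3, epochs = 2,
                               n_frozen_blocks = 0, seed = 1))
  expect_identical(config_digest(unclass(bl$model$spec)),
                   config_digest(unclass(ft$model$spec)))
})

test_that("shuffled labels yield chance-level test error", {
  ds <- toy_dataset(seed = 12, n_subjects = 3, cycles = 2)
  parts <- toy_labeled(ds, step = 4)
  shuf <- parts$train
  set.seed(1)
  shuf$targets <- shuf$targets[sample(dim(shuf$targets)[1]), , ,
                               drop = FALSE]
  sp <- toy_model_spec(n_in = 18L)
  bl <- train_baseline(shuf, parts$val, sp,
                       pretrain_spec(lr = 1e-3, batch_size = 32,
                                     epochs = 8, seed = 3))
  err <- test_mse(bl, parts$test)
  base_var <- mean((parts$test$targets -
                    mean(parts$train$targets))^2)
  expect_gt(err, 0.5 * base_var)    # no learnable signal beyond the mean
})

test_that("checkpoints round-trip through disk", {
  sp <- toy_model_spec()
  m <- init_model(sp, seed = 1)
  m$stage <- "pretrain"
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, stats = list(mean = 1:4, sd = rep(1, 4)),
                  provenance = list(stage = "pretrain", seed = 1))
  back <- load_checkpoint(path)
  expect_identical(back$model$params, m$params)
  expect_identical(back$provenance$stage, "pretrain")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(x = 1), bad)
  expect_error(load_checkpoint(bad), class = "gaitssl_schema_error")
})
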