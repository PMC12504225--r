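# Shared toy fixtures, built in code.

toy_model_spec <- function(window = 16L, n_in = 4L, n_out = n_in,
                           blocks = 2L) {
  model_spec(window = window, patch_length = 1L, n_channels_in = n_in,
             n_channels_out = n_out, d_model = 8L, n_blocks = blocks,
             n_heads = 2L, ffn_dim = 12L, dropout = 0.1)
}

# tiny synthetic dataset for fast training tests
toy_dataset <- function(seed = 5L, n_subjects = 4L, cycles = 2L,
                        noise = 0.5) {
  generate_dataset(synthetic_config(n_subjects = n_subjects,
                                    cycles_per_condition = cycles,
                                    cycle_length = 50L,
                                    angle_noise_sd = noise, seed = seed))
}

# labeled knee windows from a toy dataset, standardized and split
toy_labeled <- function(ds, window = 16L, step = 8L, seed = 3L) {
  pair <- joint_pair("knee")
  lab <- windows_from_dataset(ds, window, step, channels = pair$angles,
                              moments = pair$moments)
  parts <- split_dataset(lab, split_spec(seed = seed))
  parts$train <- standardize(parts$train)
  parts$val <- gaitssl:::apply_stats(parts$val, parts$train$stats)
  parts$test <- gaitssl:::apply_stats(parts$test, parts$train$stats)
  parts
}

toy_pretrained <- function(ds, window = 16L, step = 8L, epochs = 5L,
                           seed = 1L, blocks = 2L) {
  uw <- standardize(windows_from_dataset(ds, window, step))
  sp <- toy_model_spec(window = window, n_in = 18L, blocks = blocks)
  pretrain(uw, sp, pretrain_spec(lr = 1e-3, epochs = epochs, seed = seed))
}
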