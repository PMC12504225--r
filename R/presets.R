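# Named run presets: the full-scale configuration ("paper_shape") and the
# desk-scale demonstration ("desk_demo") that exercises the whole chain —
# simulate, prepare, pretrain, fine-tune vs baseline, evaluate — on one CPU.

#' Desk-scale protocol components
#'
#' The desk protocol runs the complete two-stage pipeline at a size a single
#' CPU handles in minutes: 12 subjects x 3 speeds x 3 cycles on the 100-sample
#' grid (2,160 windows of 24 samples, stride 4), a 2-block/16-wide/2-head
#' Transformer, 100 pre-training epochs at Adam 1e-3, and 30-epoch
#' fine-tuning/baseline runs at batch 16.  Moment labels are restricted to 2
#' subjects; the other 10 subjects form the test set, so the benchmark probes
#' generalization from scarce labels while pre-training sees every subject's
#' unlabeled kinematics.
#'
#' @param seed Master seed for the synthetic dataset.
#' @return `desk_dataset_config`: a [synthetic_config()]; `desk_model_spec`:
#'   a [model_spec()]; `desk_pretrain_spec`, `desk_baseline_spec`:
#'   [pretrain_spec()]s; `desk_finetune_spec`: a [finetune_spec()].
#' @export
desk_dataset_config <- function(seed = 7L) {
  synthetic_config(n_subjects = 12L, cycles_per_condition = 3L,
                   cycle_length = 100L, seed = seed)
}

#' @rdname desk_dataset_config
#' @export
desk_model_spec <- function() {
  model_spec(window = 24L, patch_length = 1L, n_channels_in = 18L,
             d_model = 16L, n_blocks = 2L, n_heads = 2L, ffn_dim = 32L,
             dropout = 0.1)
}

#' @rdname desk_dataset_config
#' @param train_seed Seed for the training run.
#' @export
desk_pretrain_spec <- function(train_seed = 1L) {
  pretrain_spec(lr = 1e-3, batch_size = 64L, epochs = 100L,
                seed = train_seed)
}

#' @rdname desk_dataset_config
#' @export
desk_finetune_spec <- function(train_seed = 1L) {
  finetune_spec(lr = 1e-3, batch_size = 16L, epochs = 30L,
                n_frozen_blocks = 0L, early_stopping_patience = 30L,
                plateau_patience = 3L, freeze_embedding = FALSE,
                seed = train_seed)
}

#' @rdname desk_dataset_config
#' @export
desk_baseline_spec <- function(train_seed = 1L) {
  pretrain_spec(lr = 1e-3, batch_size = 16L, epochs = 30L, seed = train_seed)
}

#' Desk windowing parameters (window length, stride)
#' @rdname desk_dataset_config
#' @export
desk_window <- function() list(window = 24L, step = 4L)

#' Full-scale ("paper-shape") configuration set
#'
#' The reference configuration: 55 subjects in five age strata, 897 cycles on
#' the 100-sample grid (unequal per-condition counts), 64-sample windows at
#' stride 1 (33,189 windows), the 24-wide/8-block/12-head architecture, 2000
#' pre-training and 500 fine-tuning epochs at learning rates 1e-4/1e-6.
#' Returned as configuration objects only; running it is a multi-hour job.
#'
#' @param seed Master dataset seed.
#' @return Named list of configuration objects.
#' @export
paper_shape_config <- function(seed = 1L) {
  list(dataset = synthetic_config(n_subjects = 55L,
                                  cycles_per_condition = 5L,
                                  cycle_length = 100L,
                                  total_cycles = 897L, seed = seed),
       window = list(window = 64L, step = 1L),
       model = model_spec(),
       pretrain = pretrain_spec(seed = seed),
       finetune = finetune_spec(seed = seed),
       split = split_spec(seed = seed))
}

#' Run a named preset end to end
#'
#' `"desk_demo"` executes the full chain at desk scale: synthesize the
#' dataset, prepare windows, pre-train, fine-tune against the from-scratch
#' baseline at several label fractions, and write a JSON summary plus CSV
#' logs under `out_dir`.  `"paper_shape"` writes the full-scale
#' configuration files (dataset, windowing, model, training) without
#' executing training.
#'
#' @param name `"desk_demo"` or `"paper_shape"`.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param fractions Label fractions for the desk comparison.
#' @param seeds Training seeds for the desk comparison.
#' @return Invisibly, the summary list (desk_demo) or the configuration list
#'   (paper_shape).
#' @export
run_preset <- function(name = c("desk_demo", "paper_shape"), out_dir,
                       seed = 7L, fractions = c(0.05, 0.2, 1.0),
                       seeds = 1:2) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop_invalid("unknown preset '", name[1],
                 "'; available: desk_demo, paper_shape"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "paper_shape") {
    cfg <- paper_shape_config(seed)
    digest <- config_digest(cfg)
    writeLines(jsonlite::toJSON(c(list(digest = digest), cfg),
                                auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, force = TRUE),
               file.path(out_dir, "paper_shape_config.json"))
    return(invisible(c(cfg, digest = digest)))
  }
  ds <- generate_dataset(desk_dataset_config(seed))
  write_gait_dataset(ds, file.path(out_dir, "dataset"))
  w <- desk_window()
  bm <- make_benchmark(ds, "knee", w$window, w$step,
                       split = split_spec(seed = seed + 4L),
                       labeled_subjects = 2L)
  pt <- pretrain(bm$pretrain, desk_model_spec(), desk_pretrain_spec(seed))
  utils::write.csv(pt$log, file.path(out_dir, "pretrain_log.csv"),
                   row.names = FALSE)
  curve <- efficiency_curve(bm, pt, fractions, seeds,
                            fspec = desk_finetune_spec(),
                            bspec = desk_baseline_spec())
  utils::write.csv(curve, file.path(out_dir, "efficiency.csv"),
                   row.names = FALSE)
  sm <- summarize_efficiency(curve)
  ssl <- sm$mean_mse[sm$arm == "ssl"]
  base <- sm$mean_mse[sm$arm == "baseline"]
  summary <- list(
    preset = "desk_demo", seed = seed, dataset_digest = ds$digest,
    n_windows_pretrain = dim(bm$pretrain$inputs)[1],
    fractions = sort(fractions), seeds = seeds,
    mean_test_mse_ssl = ssl, mean_test_mse_baseline = base,
    percent_improvement = as.numeric(percent_improvement(base, ssl)),
    ssl_never_worse = all(ssl <= base))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "summary.json"))
  invisible(summary)
}
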