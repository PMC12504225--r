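# Metrics, improvement summaries, peak/valley analysis, aggregation, and the
# evaluation harness plumbing.

test_that("mse and mae match hand-computed values and loop oracles", {
  expect_equal(mse(c(0, 0), c(1, 3)), 5.0)
  expect_equal(mae(c(0, 0), c(1, 3)), 2.0)
  expect_equal(mse(1:5, 1:5), 0)
  expect_equal(mae(1:5, 1:5), 0)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1000, 1)
    y <- rnorm(n); yh <- rnorm(n)
    s_mse <- 0; s_mae <- 0
    for (i in seq_len(n)) {
      s_mse <- s_mse + (y[i] - yh[i])^2
      s_mae <- s_mae + abs(y[i] - yh[i])
    }
    expect_equal(mse(y, yh), s_mse / n, tolerance = 1e-12)
    expect_equal(mae(y, yh), s_mae / n, tolerance = 1e-12)
    expect_lte(mae(y, yh), sqrt(mse(y, yh)))       # Jensen
  }
  expect_error(mse(1:3, 1:4), class = "gaitssl_invalid_argument")
  expect_error(mae(numeric(0), numeric(0)),
               class = "gaitssl_invalid_argument")
})

test_that("percent improvement reproduces reported error reductions", {
  expect_equal(percent_improvement(0.018, 0.011), 38.9)
  expect_equal(percent_improvement(0.045, 0.025), 44.4)
  expect_equal(percent_improvement(0.187, 0.142), 24.1)
  expect_equal(percent_improvement(3, 3), 0)
  expect_error(percent_improvement(0, 1), class = "gaitssl_invalid_argument")
})

test_that("improvement summaries aggregate pairs correctly", {
  one <- improvement_summary(list(c(0.05, 0.03)))
  expect_equal(unname(one["min"]), unname(one["max"]))
  expect_equal(unname(one["mean"]), 40)
  expect_error(improvement_summary(list()),
               class = "gaitssl_invalid_argument")
})

test_that("peak/valley analysis locates extrema and scales errors", {
  t <- (0:99) / 100
  obs <- sin(2 * pi * t)
  tab <- peak_valley_report(obs, obs)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$type, c("peak", "valley"))
  expect_equal(sort(tab$location_pct), c(25, 75))
  expect_true(all(tab$abs_error == 0))

  tab9 <- peak_valley_report(obs, 0.9 * obs)
  expect_equal(tab9$rel_error_pct, c(10, 10), tolerance = 1e-9)

  expect_warning(flat <- peak_valley_report(rep(1, 50), rep(1, 50)),
                 "no strict local extrema")
  expect_equal(nrow(flat), 0)
})

test_that("multi-seed aggregation averages element-wise", {
  r1 <- list(mse = 0.02, mae = 0.1)
  r2 <- list(mse = 0.04, mae = 0.3)
  agg <- aggregate_runs(list(r1, r2))
  expect_equal(agg$mean$mse, 0.03)
  expect_equal(agg$mean$mae, 0.2)
  expect_equal(agg$n_seeds, 2)
  one <- aggregate_runs(list(r1))
  expect_equal(one$mean, r1)
  # oracle: explicit loop over seeds
  vals <- c(0.011, 0.013, 0.017)
  reports <- lapply(vals, function(v) list(mse = v))
  acc <- 0
  for (v in vals) acc <- acc + v
  expect_equal(aggregate_runs(reports)$mean$mse, acc / 3)
  expect_error(aggregate_runs(list(r1, list(mse = 1))),
               class = "gaitssl_schema_error")
})

test_that("the evaluation report carries per-joint metrics and extrema", {
  ds <- toy_dataset(seed = 13, n_subjects = 3, cycles = 2)
  pt <- toy_pretrained(ds, epochs = 3)
  parts <- toy_labeled(ds)
  ft <- finetune(pt, parts$train, parts$val,
                 finetune_spec(lr = 1e-3, epochs = 5, n_frozen_blocks = 0,
                               freeze_embedding = FALSE, seed = 1))
  rep <- evaluate_model(ft, parts$test)
  expect_named(rep$mse, c("LKneeFlex", "RKneeFlex"))
  expect_true(all(rep$mse >= 0))
  expect_true(all(rep$mae <= sqrt(rep$mse) + 1e-12))
  expect_equal(nrow(rep$per_timestep_mae), 16)
})

test_that("a degenerate efficiency curve reduces to two single MSEs", {
  ds <- toy_dataset(seed = 14, n_subjects = 3, cycles = 1)
  pt <- toy_pretrained(ds, epochs = 2)
  parts <- toy_labeled(ds)
  bm <- list(pretrain = NULL, train = parts$train, val = parts$val,
             test = parts$test)
  curve <- efficiency_curve(
    bm, pt, fractions = 1.0, seeds = 1,
    fspec = finetune_spec(lr = 1e-3, epochs = 2, n_frozen_blocks = 0,
                          freeze_embedding = FALSE),
    bspec = pretrain_spec(lr = 1e-3, epochs = 2))
  expect_equal(nrow(curve), 2)
  expect_setequal(curve$arm, c("ssl", "baseline"))
  expect_true(all(curve$test_mse >= 0))
  expect_error(efficiency_curve(bm, pt, fractions = 1.5, seeds = 1),
               class = "gaitssl_invalid_argument")
})

test_that("presets expose stable configurations and reject unknown names", {
  cfg1 <- paper_shape_config(seed = 1)
  cfg2 <- paper_shape_config(seed = 1)
  expect_identical(config_digest(lapply(cfg1, unclass)),
                   config_digest(lapply(cfg2, unclass)))
  expect_equal(cfg1$dataset$total_cycles, 897L)
  expect_equal(cfg1$window$window, 64L)
  expect_equal(cfg1$model$n_blocks, 8L)
  expect_equal(cfg1$pretrain$epochs, 2000L)
  expect_equal(cfg1$finetune$epochs, 500L)
  expect_equal(cfg1$finetune$lr * 100, cfg1$pretrain$lr)
  dir <- withr::local_tempdir()
  out <- run_preset("paper_shape", dir, seed = 1)
  expect_true(file.exists(file.path(dir, "paper_shape_config.json")))
  expect_error(run_preset("nope", dir), class = "gaitssl_invalid_argument")
})
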