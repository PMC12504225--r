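# Metrics and evaluation designs: MSE/MAE, percent improvements and their
# summaries, peak/valley error tables, label-efficiency curves, cross-joint
# transfer matrices, and multi-seed aggregation.

#' Mean squared error
#'
#' `MSE = (1/N) * sum_i (y_i - yhat_i)^2`.
#'
#' @param y,y_hat Equal-length numeric vectors (observed, predicted).
#' @return Non-negative scalar.
#' @export
mse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) == 0)
    stop_invalid("y and y_hat must be non-empty and of equal length")
  mean((y - y_hat)^2)
}

#' Mean absolute error
#'
#' `MAE = (1/N) * sum_i |y_i - yhat_i|`.
#'
#' @inheritParams mse
#' @return Non-negative scalar.
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) == 0)
    stop_invalid("y and y_hat must be non-empty and of equal length")
  mean(abs(y - y_hat))
}

#' Percent improvement of an error metric over a baseline
#'
#' `100 * (baseline - improved) / baseline`, rounded to `digits` decimals.
#'
#' @param baseline Positive baseline error.
#' @param improved Non-negative improved error.
#' @param digits Decimals to report (default 1).
#' @return Percentage (positive = improvement).
#' @export
percent_improvement <- function(baseline, improved, digits = 1) {
  if (any(baseline <= 0)) stop_invalid("baseline must be positive")
  round(100 * (baseline - improved) / baseline, digits)
}

#' Min / max / mean percent improvement over a set of metric pairs
#'
#' @param pairs List of `c(baseline, improved)` pairs (or a 2-column matrix,
#'   rows = pairs).
#' @return Named numeric vector `min`, `max`, `mean`, at two decimals.
#' @export
improvement_summary <- function(pairs) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  if (length(pairs) == 0) stop_invalid("pairs must be non-empty")
  imp <- vapply(pairs, function(p)
    percent_improvement(p[1], p[2], digits = 10), numeric(1))
  c(min = round(min(imp), 2), max = round(max(imp), 2),
    mean = round(mean(imp), 2))
}

#' Peak/valley error table for a cycle-averaged moment curve
#'
#' Locates strict local maxima and minima of the observed curve (within a
#' half-window, default 5% of the cycle) and reports, per extremum, its
#' location on the 0-100% grid, the observed value, the absolute prediction
#' error, and the relative error `100 * |pred - obs| / |obs|`.
#'
#' @param observed,predicted Numeric vectors on the same normalized-cycle
#'   grid (N·m/kg).
#' @param half_window Neighbourhood half-width for the strict local
#'   comparison, as a fraction of the cycle (default 0.05).
#' @return data.frame with columns `type` ("peak"/"valley"), `location_pct`,
#'   `observed`, `abs_error`, `rel_error_pct`.
#' @export
peak_valley_report <- function(observed, predicted, half_window = 0.05) {
  if (length(observed) != length(predicted))
    stop_invalid("curves must share the grid")
  n <- length(observed)
  hw <- max(1L, round(half_window * n))
  rows <- list()
  if (n <= 2 * hw) return(data.frame(type = character(0),
                                     location_pct = numeric(0),
                                     observed = numeric(0),
                                     abs_error = numeric(0),
                                     rel_error_pct = numeric(0)))
  # interior points only: endpoints lack a two-sided neighbourhood
  for (i in (hw + 1L):(n - hw)) {
    nb <- setdiff((i - hw):(i + hw), i)
    if (all(observed[i] > observed[nb])) type <- "peak"
    else if (all(observed[i] < observed[nb])) type <- "valley"
    else next
    err <- abs(predicted[i] - observed[i])
    rows[[length(rows) + 1L]] <- data.frame(
      type = type, location_pct = 100 * (i - 1) / n,
      observed = observed[i], abs_error = err,
      rel_error_pct = if (abs(observed[i]) > 0) 100 * err / abs(observed[i])
                      else NA_real_)
  }
  if (!length(rows)) {
    warning("observed curve has no strict local extrema; empty table")
    return(data.frame(type = character(0), location_pct = numeric(0),
                      observed = numeric(0), abs_error = numeric(0),
                      rel_error_pct = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Aggregate per-seed metric reports into their mean
#'
#' Element-wise mean of numeric entries across reports sharing an identical
#' structure; per-seed values and the seed count are retained.
#'
#' @param per_seed_reports Non-empty list of identically structured named
#'   lists/vectors of numeric metrics.
#' @return List with `mean` (element-wise means), `per_seed`, `n_seeds`.
#' @export
aggregate_runs <- function(per_seed_reports) {
  if (!length(per_seed_reports)) stop_invalid("need at least one report")
  nm <- names(unlist(per_seed_reports[[1]]))
  flat <- lapply(per_seed_reports, function(r) {
    u <- unlist(r)
    if (!identical(names(u), nm))
      stop_schema("reports have heterogeneous structure")
    u
  })
  m <- colMeans(do.call(rbind, flat))
  list(mean = utils::relist(m, per_seed_reports[[1]]),
       per_seed = per_seed_reports, n_seeds = length(per_seed_reports))
}

# ---------------------------------------------------------------------------
# benchmark harness: shared data preparation for the two arms

#' Prepare a fixed benchmark from a synthetic dataset
#'
#' Builds the standardized pre-training window set (18 channels) and, for a
#' joint, the labeled angle/moment windows split into train/val/test.  The
#' split and normalization are computed once so every arm and label fraction
#' sees identical validation and test windows.
#'
#' Two labeling protocols are available.  With `labeled_subjects = NULL`
#' (default) the labeled windows are partitioned by `split` in the usual
#' 70/20/10 way.  With `labeled_subjects = k`, moment labels are restricted
#' to `k` randomly chosen subjects (emulating scarce inverse-dynamics
#' labels): their cycles are split into train/val, every other subject's
#' windows form the test set, and pre-training still sees all subjects'
#' unlabeled windows.
#'
#' @param dataset A `gait_dataset`.
#' @param joint `"knee"`, `"ankle"` or `"hip"`, or a list with `angles` and
#'   `moments` channel vectors (e.g. single channels for cross-joint cells).
#' @param window,step Windowing parameters.
#' @param split A [split_spec()] (also supplies the seed for the
#'   scarce-label protocol).
#' @param labeled_subjects Optional number of label-carrying subjects.
#' @param val_fraction Fraction of labeled cycles held out for validation in
#'   the scarce-label protocol.
#' @return List: `pretrain` (unlabeled standardized windows), `train`,
#'   `val`, `test` (labeled standardized windows), `stats`.
#' @export
make_benchmark <- function(dataset, joint = "knee", window = 32L, step = 2L,
                           split = split_spec(), labeled_subjects = NULL,
                           val_fraction = 0.25) {
  pair <- if (is.character(joint)) joint_pair(joint) else joint
  unlab <- windows_from_dataset(dataset, window, step)
  unlab <- standardize(unlab)
  lab <- windows_from_dataset(dataset, window, step,
                              channels = pair$angles, moments = pair$moments)
  if (is.null(labeled_subjects)) {
    parts <- split_dataset(lab, split)
  } else {
    subj <- sub("_.*$", "", lab$provenance$cycle_id)
    subjects <- unique(subj)
    if (labeled_subjects >= length(subjects) - 1)
      stop_invalid("labeled_subjects must leave at least one test subject")
    lab_subj <- with_substream(split$seed, "label-subjects", 0L,
                               sample(subjects, labeled_subjects))
    lab_idx <- which(subj %in% lab_subj)
    cyc <- unique(lab$provenance$cycle_id[lab_idx])
    n_val <- max(1L, round(val_fraction * length(cyc)))
    val_cyc <- with_substream(split$seed, "label-val", 0L,
                              sample(cyc, n_val))
    parts <- list(
      train = subset_windows(lab, lab_idx[!lab$provenance$cycle_id[lab_idx]
                                          %in% val_cyc]),
      val = subset_windows(lab, lab_idx[lab$provenance$cycle_id[lab_idx]
                                        %in% val_cyc]),
      test = subset_windows(lab, which(!subj %in% lab_subj)))
  }
  parts$train <- standardize(parts$train)
  parts$val <- apply_stats(parts$val, parts$train$stats)
  parts$test <- apply_stats(parts$test, parts$train$stats)
  list(pretrain = unlab, train = parts$train, val = parts$val,
       test = parts$test, stats = parts$train$stats)
}

#' Label-efficiency curve: SSL fine-tuning vs from-scratch baseline
#'
#' For every label fraction and seed, fine-tunes the pre-trained model and
#' trains the baseline on the same subsampled training windows, then
#' evaluates both on the identical fixed test set.
#'
#' @param benchmark Result of [make_benchmark()].
#' @param pretrained Result of [pretrain()] on `benchmark$pretrain` (shared
#'   across fractions; per-seed checkpoints may be supplied as a list keyed
#'   by seed).
#' @param fractions Ascending label fractions in (0, 1].
#' @param seeds Integer vector of training seeds.
#' @param fspec A [finetune_spec()] template (seed/fraction overridden).
#' @param bspec A [pretrain_spec()]-style baseline configuration.
#' @return data.frame of class `efficiency_curve`: `fraction`, `seed`,
#'   `arm` ("ssl"/"baseline"), `test_mse`.
#' @export
efficiency_curve <- function(benchmark, pretrained, fractions, seeds,
                             fspec = finetune_spec(), bspec = pretrain_spec()) {
  if (any(fractions <= 0 | fractions > 1))
    stop_invalid("fractions must lie in (0, 1]")
  fractions <- sort(fractions)
  rows <- list()
  for (seed in seeds) {
    ck <- if (!is.null(pretrained$model)) pretrained
          else pretrained[[as.character(seed)]]
    for (f in fractions) {
      fs <- fspec; fs$seed <- as.integer(seed); fs$label_fraction <- f
      fit <- finetune(ck, benchmark$train, benchmark$val, fs)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, seed = seed, arm = "ssl",
        test_mse = test_mse(fit, benchmark$test))
      bs <- bspec; bs$seed <- as.integer(seed)
      bl <- train_baseline(benchmark$train, benchmark$val, ck$model$spec,
                           bs, label_fraction = f)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, seed = seed, arm = "baseline",
        test_mse = test_mse(bl, benchmark$test))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("efficiency_curve", "data.frame")
  out
}

#' Mean test MSE per (fraction, arm) of an efficiency curve
#' @param curve An `efficiency_curve`.
#' @return data.frame `fraction`, `arm`, `mean_mse`.
#' @export
summarize_efficiency <- function(curve) {
  agg <- stats::aggregate(test_mse ~ fraction + arm, data = curve, FUN = mean)
  names(agg)[3] <- "mean_mse"
  agg[order(agg$fraction, agg$arm), ]
}

#' Cross-joint transfer matrix of test MSEs
#'
#' For each (input angle channel, target moment channel) pair among the six
#' sagittal joints, fine-tunes a single-channel model from the shared
#' pre-trained checkpoint and records its test MSE, yielding the 6 x 6
#' matrix whose diagonal holds the same-joint mappings.
#'
#' @param dataset A `gait_dataset`.
#' @param pretrained Result of [pretrain()] on this dataset's windows.
#' @param window,step Windowing parameters (matching the pre-training
#'   preparation).
#' @param split A [split_spec()]; the same split is reused for every cell so
#'   all 36 models share their test windows' provenance structure.
#' @param fspec A [finetune_spec()] template (its `label_fraction` and
#'   `seed` apply to every cell).
#' @return 6 x 6 matrix, rows = input angle joint, columns = target moment
#'   joint, in [moment_joints()] order.
#' @export
cross_joint_matrix <- function(dataset, pretrained, window = 32L, step = 2L,
                               split = split_spec(), fspec = finetune_spec()) {
  joints <- moment_joints()
  M <- matrix(NA_real_, 6, 6, dimnames = list(input = joints,
                                              target = joints))
  for (i in seq_len(6)) {
    for (j in seq_len(6)) {
      lab <- windows_from_dataset(
        dataset, window, step,
        channels = unname(.moment_angle_channel[joints[i]]),
        moments = joints[j])
      parts <- split_dataset(lab, split)
      parts$train <- standardize(parts$train)
      parts$val <- apply_stats(parts$val, parts$train$stats)
      parts$test <- apply_stats(parts$test, parts$train$stats)
      fit <- finetune(pretrained, parts$train, parts$val, fspec)
      M[i, j] <- test_mse(fit, parts$test)
    }
  }
  M
}

#' Per-joint evaluation report for a fitted model
#'
#' Computes MSE and MAE per target channel on the test windows, plus a
#' per-time-step mean absolute error curve and peak/valley tables on the
#' window-averaged moment curves.
#'
#' @param fit Result of [finetune()] or [train_baseline()].
#' @param test A labeled `window_set`.
#' @return List of class `metrics_report`: `mse`, `mae` (named per target
#'   channel), `overall_mse`, `per_timestep_mae`, `peak_valley` (list of
#'   tables), `n_samples`.
#' @export
evaluate_model <- function(fit, test) {
  pred <- predict_moments(fit$model, test)
  obs <- test$targets
  k <- dim(obs)[3]
  nms <- test$target_names %||% paste0("target", seq_len(k))
  ms <- ma <- stats::setNames(numeric(k), nms)
  pv <- stats::setNames(vector("list", k), nms)
  pt <- matrix(0, dim(obs)[2], k, dimnames = list(NULL, nms))
  for (c in seq_len(k)) {
    ms[c] <- mse(as.vector(obs[, , c]), as.vector(pred[, , c]))
    ma[c] <- mae(as.vector(obs[, , c]), as.vector(pred[, , c]))
    pt[, c] <- colMeans(abs(obs[, , c] - pred[, , c]))
    pv[[c]] <- peak_valley_report(colMeans(obs[, , c]),
                                  colMeans(pred[, , c]))
  }
  structure(list(mse = ms, mae = ma, overall_mse = mean((obs - pred)^2),
                 per_timestep_mae = pt, peak_valley = pv,
                 n_samples = length(obs)),
            class = "metrics_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
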