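# From cycles to model-ready windows: zero-phase low-pass filtering, time
# normalization onto the 0-100% grid, sliding-window segmentation,
# per-channel standardization, and grouped train/val/test splitting.

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward ([signal::filtfilt]),
#' so the output is zero-phase and the DC component is preserved.  Filtering
#' is always applied to whole cycles before windowing.
#'
#' @param series time x channels numeric matrix (a vector is treated as one
#'   channel).
#' @param cutoff_hz Cutoff frequency, Hz (must be below Nyquist).
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Filtered matrix of the same shape.
#' @export
lowpass_filter <- function(series, cutoff_hz = 15, sample_rate_hz = 100) {
  if (cutoff_hz >= sample_rate_hz / 2)
    stop_invalid("cutoff_hz must be below the Nyquist frequency ",
                 sample_rate_hz / 2, " Hz")
  v <- is.null(dim(series))
  if (v) series <- matrix(series, ncol = 1L)
  n <- nrow(series)
  if (n < 8) stop_invalid("series too short for the filter warm-up")
  bf <- signal::butter(4, cutoff_hz / (sample_rate_hz / 2), type = "low")
  # odd-reflection padding suppresses the forward/backward edge transients
  p <- min(n - 1L, 27L)
  out <- apply(series, 2L, function(x) {
    xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x,
            2 * x[n] - rev(x[(n - p):(n - 1)]))
    signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(series))
  dimnames(out) <- dimnames(series)
  if (v) out[, 1L] else out
}

#' Resample a cycle onto a uniform 0-100% grid
#'
#' Linear interpolation onto `n_points` equally spaced positions spanning the
#' input; the first and last input samples map to the first and last output
#' samples.
#'
#' @param cycle_samples time x channels matrix (or vector).
#' @param n_points Target number of samples (>= 2).
#' @return `n_points` x channels matrix.
#' @export
time_normalize <- function(cycle_samples, n_points = 100L) {
  v <- is.null(dim(cycle_samples))
  if (v) cycle_samples <- matrix(cycle_samples, ncol = 1L)
  n_in <- nrow(cycle_samples)
  if (n_in < 2) stop_invalid("input must have at least 2 samples")
  if (n_points < 2) stop_invalid("n_points must be >= 2")
  xout <- seq(1, n_in, length.out = n_points)
  out <- apply(cycle_samples, 2L, function(y)
    approx(seq_len(n_in), y, xout = xout)$y)
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(cycle_samples))
  colnames(out) <- colnames(cycle_samples)
  if (v) out[, 1L] else out
}

#' Cut aligned cycles into fixed-length sliding windows
#'
#' Each cycle of length `T >= window` yields `floor((T - window)/step) + 1`
#' windows starting at offsets `0, step, 2*step, ...`; windows never span
#' cycle boundaries.  Cycles shorter than `window` are skipped with a
#' warning.  Optional target traces are windowed identically, index-aligned
#' with the inputs.
#'
#' @param cycles Named list of time x channels matrices.
#' @param window Window length in samples (default 64).
#' @param step Stride between successive window starts (default 1, i.e.
#'   maximal overlap).
#' @param targets Optional named list of time x k target matrices aligned
#'   with `cycles`.
#' @return Object of class `window_set`: `inputs` (n x window x channels
#'   array), optional `targets`, `provenance` data.frame (`cycle_id`,
#'   `start`, 1-based), `channel_names`, `target_names`.
#' @export
make_windows <- function(cycles, window = 64L, step = 1L, targets = NULL) {
  if (window < 1 || step < 1) stop_invalid("window and step must be >= 1")
  if (is.null(names(cycles))) names(cycles) <- sprintf("cycle%03d",
                                                       seq_along(cycles))
  ch <- colnames(cycles[[1]])
  counts <- vapply(cycles, function(m) {
    if (nrow(m) < window) 0L else
      as.integer((nrow(m) - window) %/% step + 1L)
  }, integer(1))
  if (any(counts == 0L))
    warning(sum(counts == 0L), " cycle(s) shorter than the window were skipped")
  n <- sum(counts)
  if (n == 0L) stop_invalid("no cycle is long enough for the requested window")
  nc <- ncol(cycles[[1]])
  inputs <- array(NA_real_, c(n, window, nc))
  tg <- NULL
  if (!is.null(targets)) {
    nt <- ncol(targets[[1]])
    tg <- array(NA_real_, c(n, window, nt))
  }
  prov <- data.frame(cycle_id = character(n), start = integer(n),
                     stringsAsFactors = FALSE)
  i <- 0L
  for (id in names(cycles)) {
    m <- cycles[[id]]
    if (nrow(m) < window) next
    starts <- seq(1L, nrow(m) - window + 1L, by = step)
    for (s in starts) {
      i <- i + 1L
      inputs[i, , ] <- m[s:(s + window - 1L), ]
      if (!is.null(tg)) tg[i, , ] <- targets[[id]][s:(s + window - 1L), ]
      prov$cycle_id[i] <- id
      prov$start[i] <- s
    }
  }
  structure(list(inputs = inputs, targets = tg, provenance = prov,
                 channel_names = ch,
                 target_names = if (!is.null(targets))
                   colnames(targets[[1]]),
                 stats = NULL),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$inputs)
  cat("<window_set>", d[1], "windows of", d[2], "x", d[3],
      if (!is.null(x$targets)) "(with targets)" else "(unlabeled)",
      if (!is.null(x$stats)) "[standardized]" else "", "\n")
  invisible(x)
}

n_windows <- function(ws) dim(ws$inputs)[1]

subset_windows <- function(ws, idx) {
  out <- ws
  out$inputs <- ws$inputs[idx, , , drop = FALSE]
  if (!is.null(ws$targets)) out$targets <- ws$targets[idx, , , drop = FALSE]
  out$provenance <- ws$provenance[idx, , drop = FALSE]
  out
}

#' Per-channel standardization from training-set statistics
#'
#' Z-scores each input channel using mean/s.d. computed on `stats_source`
#' (the training partition; defaults to `windows` itself).  Zero-variance
#' channels get their scale clamped to 1 with a warning.  Targets are never
#' standardized, so moments remain in N·m/kg.
#'
#' @param windows A `window_set`.
#' @param stats_source A `window_set` supplying the statistics, or `NULL`.
#' @return The standardized `window_set`, with `stats` (`mean`, `sd`)
#'   recorded for the inverse transform.
#' @export
standardize <- function(windows, stats_source = NULL) {
  src <- if (is.null(stats_source)) windows else stats_source
  nc <- dim(windows$inputs)[3]
  mu <- sg <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- src$inputs[, , c]
    mu[c] <- mean(v)
    sg[c] <- sd(as.vector(v))
  }
  if (any(!is.finite(sg) | sg < 1e-12)) {
    warning("zero-variance channel(s): scale clamped to 1")
    sg[!is.finite(sg) | sg < 1e-12] <- 1
  }
  out <- windows
  for (c in seq_len(nc))
    out$inputs[, , c] <- (windows$inputs[, , c] - mu[c]) / sg[c]
  out$stats <- list(mean = mu, sd = sg)
  out
}

#' @rdname standardize
#' @param standardized A standardized `window_set`.
#' @export
inverse_standardize <- function(standardized) {
  if (is.null(standardized$stats)) stop_invalid("window_set has no stats")
  out <- standardized
  for (c in seq_along(standardized$stats$mean))
    out$inputs[, , c] <- standardized$inputs[, , c] *
      standardized$stats$sd[c] + standardized$stats$mean[c]
  out$stats <- NULL
  out
}

# apply previously computed stats (e.g. train stats to val/test)
apply_stats <- function(windows, stats) {
  out <- windows
  for (c in seq_along(stats$mean))
    out$inputs[, , c] <- (windows$inputs[, , c] - stats$mean[c]) / stats$sd[c]
  out$stats <- stats
  out
}

#' Split specification for train/validation/test partitioning
#'
#' @param fractions Numeric length-3 vector (train, val, test) summing to 1.
#' @param group Unit kept whole across partitions: `"window"` (default,
#'   mirrors splitting after windowing), `"cycle"` or `"subject"`.  Note that
#'   with stride-1 windows, window-level splits leak overlapping samples
#'   between partitions; grouped splits avoid that.
#' @param seed Integer seed.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.20, 0.10),
                       group = c("window", "cycle", "subject"), seed = 1L) {
  group <- match.arg(group)
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_invalid("fractions must be three values in (0,1) summing to 1")
  structure(list(fractions = fractions, group = group,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Partition a window set into train/validation/test
#'
#' Groups (windows, cycles or subjects per `spec$group`) are randomly
#' permuted under the seed and assigned to partitions by cumulative counts,
#' so realized sizes differ from targets by less than one group and no group
#' ever appears in two partitions.
#'
#' @param windows A `window_set`.
#' @param spec A [split_spec()].
#' @return Named list of three `window_set`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(windows, spec = split_spec()) {
  n <- n_windows(windows)
  key <- switch(spec$group,
                window = as.character(seq_len(n)),
                cycle = windows$provenance$cycle_id,
                subject = sub("_.*$", "", windows$provenance$cycle_id))
  groups <- unique(key)
  g <- length(groups)
  if (g < 3) stop_invalid("need at least 3 groups to populate all partitions")
  perm <- with_substream(spec$seed, paste0("split:", spec$group), 0L,
                         sample(groups))
  n_train <- max(1L, round(spec$fractions[1] * g))
  n_val <- max(1L, round(spec$fractions[2] * g))
  if (n_train + n_val >= g) {
    n_train <- g - 2L
    n_val <- 1L
  }
  assign <- rep("test", g)
  assign[seq_len(n_train)] <- "train"
  assign[n_train + seq_len(n_val)] <- "val"
  names(assign) <- perm
  part <- assign[key]
  out <- lapply(c(train = "train", val = "val", test = "test"), function(p) {
    idx <- which(part == p)
    if (!length(idx)) stop_invalid("partition '", p, "' is empty after grouping")
    subset_windows(windows, idx)
  })
  out
}

#' Build labeled or unlabeled windows from a gait dataset
#'
#' Convenience bridge from [generate_dataset()] to [make_windows()]: selects
#' angle channels (all 18 by default) and, optionally, moment target
#' channels.
#'
#' @param dataset A `gait_dataset`.
#' @param window,step Windowing parameters.
#' @param channels Angle channels to keep (default all 18).
#' @param moments Moment channels to attach as targets (`NULL` for none).
#' @return A `window_set`.
#' @export
windows_from_dataset <- function(dataset, window = 64L, step = 1L,
                                 channels = kinematic_channels(),
                                 moments = NULL) {
  missing <- setdiff(channels, colnames(dataset$cycles[[1]]))
  if (length(missing))
    stop_schema("dataset missing channel(s): ", paste(missing, collapse = ", "))
  cyc <- lapply(dataset$cycles, function(m) m[, channels, drop = FALSE])
  tg <- NULL
  if (!is.null(moments)) {
    missing <- setdiff(moments, colnames(dataset$moments[[1]]))
    if (length(missing))
      stop_schema("dataset missing moment(s): ",
                  paste(missing, collapse = ", "))
    tg <- lapply(dataset$moments, function(m) m[, moments, drop = FALSE])
  }
  make_windows(cyc, window, step, targets = tg)
}
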