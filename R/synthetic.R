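# Synthetic multi-subject, multi-speed gait kinematics with a known
# angle -> moment forward model.  Waveforms are periodic Fourier templates per
# channel, modulated per subject (amplitude/phase perturbations) and per speed
# (amplitude scaling), plus Gaussian measurement noise.  Moments come from a
# stiffness + damping + cross-joint coupling + saturation map so that the
# angle-to-moment relation is nonlinear but learnable, with same-joint angles
# the dominant predictors.

# ---------------------------------------------------------------------------
# templates

# base oscillation amplitude (deg) and mean offset (deg) per channel; left and
# right limbs share a template half a cycle out of phase
.channel_base <- data.frame(
  channel = .kinematic_channels,
  amplitude = c(15, 8, 10, 25, 8, 30, 5, 8, 5, 15, 8, 10, 25, 8, 30, 5, 6, 5),
  offset    = c( 0, 0,  0, 15, 0, 25, 0, 0, 10,  0, 0,  0, 15, 0, 25, 5, 0, 2),
  phase0    = c(0.3, 1.1, 2.0, 0.0, 1.6, 0.8, 0.5, 1.3, 2.4,
                0.3, 1.1, 2.0, 0.0, 1.6, 0.8, 2.9, 0.7, 1.9),
  stringsAsFactors = FALSE
)

#' Default per-channel Fourier gait template
#'
#' Each of the 18 kinematic channels is a mean offset plus `K` cosine
#' harmonics with geometrically decaying amplitudes; right-side channels are
#' the left-side template shifted by half a gait cycle, giving bilateral
#' symmetry.  Speed conditions scale the oscillatory part multiplicatively.
#'
#' @param K Number of harmonics per channel (>= 2).
#' @param speed_scaling Named multiplicative amplitude factors for the three
#'   speed conditions.
#' @return An object of class `gait_template`.
#' @export
gait_template <- function(K = 4,
                          speed_scaling = c(slow = 0.85, comfortable = 1,
                                            fast = 1.15)) {
  if (K < 2) stop_invalid("K must be >= 2")
  if (!setequal(names(speed_scaling), .speed_levels))
    stop_invalid("speed_scaling must name exactly: ",
                 paste(.speed_levels, collapse = ", "))
  decay <- c(1, 0.45, 0.2, 0.08, 0.04, 0.02)[seq_len(K)]
  decay <- decay / sum(decay)
  amp <- outer(.channel_base$amplitude, decay)         # 18 x K, degrees
  phase <- matrix(0, 18, K)
  right <- grepl("^R", .channel_base$channel)
  for (k in seq_len(K)) {
    phase[, k] <- .channel_base$phase0 * k
    # half-cycle time shift for the contralateral limb: phi_k + k*pi
    phase[right, k] <- phase[right, k] + k * pi
  }
  rownames(amp) <- rownames(phase) <- .channel_base$channel
  structure(list(channels = .channel_base$channel,
                 offset = stats::setNames(.channel_base$offset,
                                          .channel_base$channel),
                 amplitude = amp, phase = phase, K = K,
                 speed_scaling = speed_scaling[.speed_levels]),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat("<gait_template> 18 channels,", x$K, "harmonics; speed scaling:",
      paste(sprintf("%s=%.2f", names(x$speed_scaling), x$speed_scaling),
            collapse = " "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# subjects

#' Generate subject profiles across the five age strata
#'
#' Subjects are allocated to the five age groups (3-6, 7-8, 9-10, 11-12,
#' >=13 years) by largest-remainder quota on the study proportions
#' 11:10:15:11:8, so `n_subjects = 55` reproduces those counts exactly.  Body
#' mass and leg length are drawn from age-group-specific distributions;
#' per-channel template perturbations (log-amplitude factor, phase offset) are
#' derived from `(seed, subject_id)` so any subject can be regenerated alone.
#'
#' Perturbation magnitudes shrink with age (gait matures through childhood),
#' so young subjects deviate most from the population template.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param amp_sd S.d. of the per-channel log-amplitude factor for the oldest
#'   stratum (default 0.25, i.e. roughly +/-25% amplitude).
#' @param phase_sd S.d. of the per-channel phase offset (rad) for the oldest
#'   stratum (default 0.5, a few percent of the cycle).
#' @return A data.frame of class `gait_subjects` with columns `subject_id`,
#'   `age_group`, `body_mass` (kg), `leg_length` (m) and list-column
#'   `perturbation` (18 x 2 matrix: `amp_log`, `phase` per channel).
#' @export
make_subject_profiles <- function(n_subjects, seed = 1L, amp_sd = 0.25,
                                  phase_sd = 0.5) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop_invalid("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  w <- .age_group_counts / sum(.age_group_counts)
  quota <- floor(n_subjects * w)
  rem <- n_subjects - sum(quota)
  if (rem > 0) {
    frac <- n_subjects * w - quota
    quota[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      quota[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  groups <- rep(.age_groups, times = quota)
  # group-specific anthropometry (means chosen to match the cohort-level
  # mean mass ~35.7 kg and leg length ~0.73 m)
  gi <- match(groups, .age_groups)
  mass_mu <- c(20, 27, 35, 45, 56)[gi]
  leg_mu  <- c(0.58, 0.67, 0.74, 0.81, 0.87)[gi]
  pert_scale <- c(1.5, 1.2, 1.0, 0.9, 0.8)[gi]
  ids <- sprintf("S%03d", seq_len(n_subjects))
  mass <- leg <- numeric(n_subjects)
  pert <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    with_substream(seed, paste0("subject:", ids[i]), 0L, {
      mass[i] <- max(10, rnorm(1, mass_mu[i], 0.12 * mass_mu[i]))
      leg[i] <- max(0.4, rnorm(1, leg_mu[i], 0.05 * leg_mu[i]))
      p <- cbind(amp_log = rnorm(18, 0, amp_sd * pert_scale[i]),
                 phase = rnorm(18, 0, phase_sd * pert_scale[i]))
      rownames(p) <- .kinematic_channels
      pert[[i]] <- p
    })
  }
  out <- data.frame(subject_id = ids, age_group = groups,
                    body_mass = mass, leg_length = leg,
                    stringsAsFactors = FALSE)
  out$perturbation <- pert
  class(out) <- c("gait_subjects", "data.frame")
  out
}

# zero-perturbation profile, used for noise-free template checks
null_profile <- function() {
  p <- cbind(amp_log = rep(0, 18), phase = rep(0, 18))
  rownames(p) <- .kinematic_channels
  out <- data.frame(subject_id = "S000", age_group = "9-10",
                    body_mass = 35, leg_length = 0.73,
                    stringsAsFactors = FALSE)
  out$perturbation <- list(p)
  class(out) <- c("gait_subjects", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# cycles

#' Synthesize one time-normalized gait cycle
#'
#' Evaluates the subject- and speed-modulated Fourier template on a uniform
#' grid of `cycle_length` points covering 0 to 100% of the gait cycle
#' (endpoint excluded, so the waveform is exactly periodic before noise), then
#' adds i.i.d. Gaussian measurement noise.
#'
#' @param profile One row of [make_subject_profiles()].
#' @param template A [gait_template()].
#' @param speed `"slow"`, `"comfortable"` or `"fast"`.
#' @param cycle_length Samples per cycle (>= 8; 100 matches a 1% grid).
#' @param noise_sd Measurement noise s.d. in degrees.
#' @param seed Integer seed for the noise draw.
#' @return `cycle_length` x 18 matrix of class `gait_cycle` (degrees), with
#'   subject/speed metadata attributes.
#' @export
synthesize_cycle <- function(profile, template, speed = "comfortable",
                             cycle_length = 100L, noise_sd = 0.5, seed = 1L) {
  if (!speed %in% .speed_levels)
    stop_invalid("unknown speed '", speed, "'; expected one of: ",
                 paste(.speed_levels, collapse = ", "))
  if (cycle_length < 8) stop_invalid("cycle_length must be >= 8")
  if (nrow(profile) != 1L) stop_invalid("profile must be a single row")
  tgrid <- (seq_len(cycle_length) - 1) / cycle_length
  pert <- profile$perturbation[[1]]
  sfac <- template$speed_scaling[[speed]]
  X <- matrix(0, cycle_length, 18,
              dimnames = list(NULL, template$channels))
  for (c in seq_len(18)) {
    osc <- 0
    for (k in seq_len(template$K))
      osc <- osc + template$amplitude[c, k] *
        cos(2 * pi * k * tgrid + template$phase[c, k] + pert[c, "phase"])
    X[, c] <- template$offset[c] + exp(pert[c, "amp_log"]) * sfac * osc
  }
  if (noise_sd > 0) {
    with_substream(seed, paste0("noise:", profile$subject_id, ":", speed), 0L, {
      X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow(X), ncol(X))
    })
  }
  structure(X, class = c("gait_cycle", class(X)),
            subject_id = profile$subject_id, speed = speed)
}

# ---------------------------------------------------------------------------
# moment forward model

#' Parameters of the synthetic angle-to-moment forward model
#'
#' Each sagittal joint moment is a saturated linear-plus-damping map of the
#' six sagittal angle channels: `m_j(t) = clamp(a_j * theta_j(t) + b_j *
#' dtheta_j(t) + sum_{k != j} c_jk * theta_k(t), +/- s_j) + noise`.  The
#' coupling matrix must be diagonally dominant (`|a_j| > sum_k |c_jk|`) so the
#' same-joint angle stays the strongest predictor of each moment.
#'
#' @param a Stiffness gains, (N·m/kg)/deg, length 6 (joint order of
#'   [moment_joints()]).
#' @param b Damping gains, (N·m/kg)/(deg/sample).
#' @param coupling 6 x 6 cross-joint gain matrix, zero diagonal.
#' @param saturation Clamp scale per joint, N·m/kg (`Inf` disables).
#' @param noise_sd Additive noise s.d., N·m/kg.
#' @return Object of class `moment_model_params`.
#' @export
moment_model_params <- function(a = c(0.050, 0.050, 0.060, 0.060, 0.035, 0.035),
                                b = rep(0.010, 6),
                                coupling = default_coupling(),
                                saturation = rep(2.0, 6),
                                noise_sd = 0.05) {
  stopifnot(length(a) == 6, length(b) == 6, length(saturation) == 6,
            all(dim(coupling) == c(6, 6)))
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  diag(coupling) <- 0
  if (any(abs(a) <= rowSums(abs(coupling))))
    stop_invalid("coupling must be diagonally dominant: |a_j| > sum_k |c_jk|")
  structure(list(a = stats::setNames(a, .moment_joints),
                 b = stats::setNames(b, .moment_joints),
                 coupling = `dimnames<-`(coupling,
                                         list(.moment_joints, .moment_joints)),
                 saturation = stats::setNames(saturation, .moment_joints),
                 noise_sd = noise_sd),
            class = "moment_model_params")
}

#' @rdname moment_model_params
#' @export
default_coupling <- function() {
  cc <- matrix(0, 6, 6, dimnames = list(.moment_joints, .moment_joints))
  # same-side knee<->ankle and knee<->hip synergies
  cc["LKneeFlex", c("LAnkleFlex", "LHipFlex")] <- 0.006
  cc["RKneeFlex", c("RAnkleFlex", "RHipFlex")] <- 0.006
  cc["LAnkleFlex", "LKneeFlex"] <- 0.008
  cc["RAnkleFlex", "RKneeFlex"] <- 0.008
  cc["LHipFlex", "LKneeFlex"] <- 0.005
  cc["RHipFlex", "RKneeFlex"] <- 0.005
  cc
}

#' Compute the six sagittal joint-moment traces for one cycle
#'
#' Applies the forward model of [moment_model_params()] to a cycle's angle
#' channels.  The angular velocity term uses a first central difference with
#' one-sided differences at the ends.
#'
#' @param cycle A `gait_cycle` (or any time x 18 matrix with the canonical
#'   channel names).
#' @param params A [moment_model_params()].
#' @param seed Integer seed for the noise draw.
#' @return time x 6 matrix of moments (N·m/kg), columns in
#'   [moment_joints()] order.
#' @export
forward_moment_model <- function(cycle, params = moment_model_params(),
                                 seed = 1L) {
  need <- unname(.moment_angle_channel)
  missing <- setdiff(need, colnames(cycle))
  if (length(missing))
    stop_schema("cycle is missing channel(s): ", paste(missing, collapse = ", "))
  theta <- cycle[, .moment_angle_channel[.moment_joints], drop = FALSE]
  n <- nrow(theta)
  dtheta <- matrix(0, n, 6)
  dtheta[2:(n - 1), ] <- (theta[3:n, , drop = FALSE] -
                          theta[1:(n - 2), , drop = FALSE]) / 2
  dtheta[1, ] <- theta[2, ] - theta[1, ]
  dtheta[n, ] <- theta[n, ] - theta[n - 1, ]
  M <- theta %*% diag(params$a) + dtheta %*% diag(params$b) +
    theta %*% t(params$coupling)
  M <- pmin(pmax(M, rep(-params$saturation, each = n)),
            rep(params$saturation, each = n))
  if (params$noise_sd > 0) {
    with_substream(seed, "moment-noise", 0L, {
      M <- M + matrix(rnorm(length(M), 0, params$noise_sd), n, 6)
    })
  }
  colnames(M) <- .moment_joints
  M
}

# ---------------------------------------------------------------------------
# dataset

#' Configuration for a synthetic gait dataset
#'
#' @param n_subjects Number of subjects.
#' @param cycles_per_condition Gait cycles per (subject, speed) condition.
#' @param cycle_length Samples per time-normalized cycle.
#' @param angle_noise_sd Kinematic measurement noise, degrees.
#' @param template A [gait_template()].
#' @param moment_params A [moment_model_params()].
#' @param amp_sd,phase_sd Subject-heterogeneity magnitudes passed to
#'   [make_subject_profiles()].
#' @param total_cycles Optional total cycle-count override; the surplus or
#'   deficit relative to `n_subjects * 3 * cycles_per_condition` is spread
#'   deterministically over the first (subject, speed) conditions, allowing
#'   totals (such as 897) that are not divisible by the condition count.
#' @param seed Master dataset seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 10L, cycles_per_condition = 4L,
                             cycle_length = 100L, angle_noise_sd = 1.0,
                             template = gait_template(),
                             moment_params = moment_model_params(),
                             amp_sd = 0.25, phase_sd = 0.5,
                             total_cycles = NULL, seed = 1L) {
  if (n_subjects < 1 || cycles_per_condition < 1)
    stop_invalid("n_subjects and cycles_per_condition must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 cycles_per_condition = as.integer(cycles_per_condition),
                 cycle_length = as.integer(cycle_length),
                 angle_noise_sd = angle_noise_sd, template = template,
                 moment_params = moment_params,
                 amp_sd = amp_sd, phase_sd = phase_sd,
                 total_cycles = if (!is.null(total_cycles))
                   as.integer(total_cycles),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a complete synthetic gait dataset
#'
#' Draws subject profiles, synthesizes time-normalized cycles for every
#' (subject, speed, repeat) condition, and computes the aligned moment traces
#' with the forward model.  Regeneration from the same config is bit-identical.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `gait_dataset`: lists `cycles` (time x 18 angle
#'   matrices, degrees) and `moments` (time x 6, N·m/kg) aligned
#'   sample-for-sample, a `meta` data.frame (`cycle_id`, `subject_id`,
#'   `speed`, `age_group`), the subject table, and provenance
#'   (`seed`, `digest`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!identical(config$template$channels, .kinematic_channels))
    stop_schema("template channels do not match the canonical 18-channel set")
  subjects <- make_subject_profiles(config$n_subjects, config$seed,
                                    config$amp_sd, config$phase_sd)
  n_cond <- config$n_subjects * 3L
  counts <- rep(config$cycles_per_condition, n_cond)
  if (!is.null(config$total_cycles)) {
    delta <- config$total_cycles - sum(counts)
    i <- 1L
    while (delta != 0L) {
      counts[i] <- counts[i] + sign(delta)
      delta <- delta - sign(delta)
      i <- if (i == n_cond) 1L else i + 1L
    }
    if (any(counts < 1)) stop_invalid("total_cycles too small for the grid")
  }
  cycles <- list(); moments <- list()
  meta <- vector("list", 0L)
  idx <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (sp in seq_along(.speed_levels)) {
      cond <- (s - 1L) * 3L + sp
      for (r in seq_len(counts[cond])) {
        idx <- idx + 1L
        cyc_seed <- substream_seed(config$seed, "cycle", idx)
        cyc <- synthesize_cycle(subjects[s, ], config$template,
                                .speed_levels[sp], config$cycle_length,
                                config$angle_noise_sd, cyc_seed)
        mom <- forward_moment_model(cyc, config$moment_params,
                                    substream_seed(config$seed, "moment", idx))
        id <- sprintf("%s_%s_c%02d", subjects$subject_id[s],
                      .speed_levels[sp], r)
        cycles[[id]] <- structure(unclass(cyc), subject_id = NULL,
                                  speed = NULL)
        moments[[id]] <- mom
        meta[[idx]] <- data.frame(cycle_id = id,
                                  subject_id = subjects$subject_id[s],
                                  speed = .speed_levels[sp],
                                  age_group = subjects$age_group[s],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta)
  cfg_for_digest <- config
  cfg_for_digest$template <- unclass(config$template)
  cfg_for_digest$moment_params <- unclass(config$moment_params)
  structure(list(cycles = cycles, moments = moments, meta = meta,
                 subjects = subjects, config = config,
                 seed = config$seed, digest = config_digest(cfg_for_digest)),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("<gait_dataset>", length(x$cycles), "cycles,",
      nrow(x$cycles[[1]]), "samples/cycle,",
      length(unique(x$meta$subject_id)), "subjects; digest",
      substr(x$digest, 1, 8), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# dataset IO (wide CSV + JSON sidecar)

#' Write / read a gait dataset as CSV plus a JSON sidecar
#'
#' The cycle store is a single wide CSV with identifying columns
#' (`cycle_id`, `subject_id`, `speed`, `t_index`), the 18 angle channels in
#' degrees, and the six moment channels in N·m/kg; `manifest.json` records
#' units, seed and config digest.
#'
#' @param dataset A `gait_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_gait_dataset` returns `dir` invisibly;
#'   `read_gait_dataset` returns a `gait_dataset` (without the generating
#'   config, which is recorded only by digest).
#' @export
write_gait_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- lapply(seq_along(dataset$cycles), function(i) {
    id <- names(dataset$cycles)[i]
    m <- dataset$meta[dataset$meta$cycle_id == id, ]
    cbind(data.frame(cycle_id = id, subject_id = m$subject_id,
                     speed = m$speed,
                     t_index = seq_len(nrow(dataset$cycles[[i]])) - 1L),
          as.data.frame(dataset$cycles[[i]]),
          as.data.frame(dataset$moments[[i]]))
  })
  tab <- data.table::rbindlist(tabs)
  data.table::fwrite(tab, file.path(dir, "cycles.csv"))
  manifest <- list(format = "gaitssl-cycles-v1",
                   n_cycles = length(dataset$cycles),
                   cycle_length = nrow(dataset$cycles[[1]]),
                   angle_channels = .kinematic_channels,
                   moment_channels = .moment_joints,
                   units = list(angles = "deg", moments = "N.m/kg"),
                   seed = dataset$seed, digest = dataset$digest)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_gait_dataset
#' @export
read_gait_dataset <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  tab <- data.table::fread(file.path(dir, "cycles.csv"))
  missing <- setdiff(.kinematic_channels, names(tab))
  if (length(missing))
    stop_schema("cycle store missing channel(s): ",
                paste(missing, collapse = ", "))
  ids <- unique(tab$cycle_id)
  cycles <- moments <- stats::setNames(vector("list", length(ids)), ids)
  meta <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- tab[tab$cycle_id == ids[i], ]
    sub <- sub[order(sub$t_index), ]
    cycles[[i]] <- as.matrix(sub[, .kinematic_channels, with = FALSE])
    moments[[i]] <- as.matrix(sub[, .moment_joints, with = FALSE])
    meta[[i]] <- data.frame(cycle_id = ids[i],
                            subject_id = sub$subject_id[1],
                            speed = sub$speed[1], age_group = NA_character_,
                            stringsAsFactors = FALSE)
  }
  structure(list(cycles = cycles, moments = moments,
                 meta = do.call(rbind, meta), subjects = NULL, config = NULL,
                 seed = manifest$seed, digest = manifest$digest),
            class = "gait_dataset")
}
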