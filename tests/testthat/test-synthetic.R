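# Synthetic gait generator: subject strata, waveform synthesis, forward
# moment model, dataset assembly and IO.

test_that("subject profiles cover the five age strata proportionally", {
  p55 <- make_subject_profiles(55, seed = 1)
  expect_equal(nrow(p55), 55)
  counts <- table(factor(p55$age_group,
                         levels = c("3-6", "7-8", "9-10", "11-12", ">=13")))
  expect_equal(as.integer(counts), c(11, 10, 15, 11, 8))
  expect_true(all(p55$body_mass > 0) && all(p55$leg_length > 0))

  p1k <- make_subject_profiles(1000, seed = 3)
  prop <- table(p1k$age_group)[c("3-6", "7-8", "9-10", "11-12", ">=13")] / 1000
  expect_true(all(abs(prop - c(11, 10, 15, 11, 8) / 55) <= 0.03))

  expect_identical(make_subject_profiles(1, seed = 7),
                   make_subject_profiles(1, seed = 7))
  expect_error(make_subject_profiles(0), class = "gaitssl_invalid_argument")
})

test_that("noise-free cycles with zero perturbation equal the template", {
  tpl <- gait_template()
  prof <- gaitssl:::null_profile()
  cyc <- synthesize_cycle(prof, tpl, "comfortable", cycle_length = 50,
                          noise_sd = 0, seed = 1)
  tgrid <- (0:49) / 50
  for (ch in c("Lkneeflex", "Rhipflex", "Trunktilt")) {
    expected <- tpl$offset[ch] +
      rowSums(sapply(seq_len(tpl$K), function(k)
        tpl$amplitude[ch, k] * cos(2 * pi * k * tgrid + tpl$phase[ch, k])))
    expect_equal(unname(cyc[, ch]), unname(expected), tolerance = 1e-12)
  }
  # periodic: the series at t = 1 wraps back to the value at t = 0
  wrap <- tpl$offset["Lkneeflex"] +
    sum(tpl$amplitude["Lkneeflex", ] * cos(2 * pi * seq_len(tpl$K) * 1 +
                                           tpl$phase["Lkneeflex", ]))
  expect_equal(unname(cyc[1, "Lkneeflex"]), unname(wrap), tolerance = 1e-9)
})

test_that("speed conditions order the waveform amplitude", {
  tpl <- gait_template()
  prof <- make_subject_profiles(1, seed = 2)
  ptp <- sapply(c("slow", "comfortable", "fast"), function(sp) {
    cyc <- synthesize_cycle(prof, tpl, sp, 100, noise_sd = 0, seed = 1)
    apply(cyc, 2, function(x) diff(range(x)))
  })
  expect_true(all(ptp[, "slow"] < ptp[, "comfortable"]))
  expect_true(all(ptp[, "comfortable"] < ptp[, "fast"]))
  expect_error(synthesize_cycle(prof, tpl, "sprint", 100),
               class = "gaitssl_invalid_argument")
  expect_identical(synthesize_cycle(prof, tpl, "fast", 100, 0.5, seed = 9),
                   synthesize_cycle(prof, tpl, "fast", 100, 0.5, seed = 9))
})

test_that("forward moment model obeys its closed-form limits", {
  prof <- gaitssl:::null_profile()
  cyc <- synthesize_cycle(prof, gait_template(), "comfortable", 60,
                          noise_sd = 0, seed = 1)
  lin <- moment_model_params(b = rep(0, 6), coupling = matrix(0, 6, 6),
                             saturation = rep(Inf, 6), noise_sd = 0)
  M <- forward_moment_model(cyc, lin)
  theta <- cyc[, c("Lkneeflex", "Rkneeflex", "Lankleflex", "Rankleflex",
                   "Lhipflex", "Rhipflex")]
  expect_equal(unname(M), unname(theta %*% diag(lin$a)), tolerance = 1e-12)

  # constant angles: the damping term contributes nothing
  const <- matrix(10, 40, 18, dimnames = list(NULL, kinematic_channels()))
  damped <- moment_model_params(b = rep(5, 6), coupling = matrix(0, 6, 6),
                                saturation = rep(Inf, 6), noise_sd = 0)
  undamped <- moment_model_params(b = rep(0, 6), coupling = matrix(0, 6, 6),
                                  saturation = rep(Inf, 6), noise_sd = 0)
  expect_equal(forward_moment_model(const, damped),
               forward_moment_model(const, undamped), tolerance = 1e-12)

  # unit-sine angle with a = 1 saturates at +/- 0.5
  sine <- matrix(0, 100, 18, dimnames = list(NULL, kinematic_channels()))
  sine[, "Lkneeflex"] <- sin(2 * pi * (0:99) / 100)
  satp <- moment_model_params(a = c(1, rep(0.5, 5)), b = rep(0, 6),
                              coupling = matrix(0, 6, 6),
                              saturation = c(0.5, rep(Inf, 5)), noise_sd = 0)
  M2 <- forward_moment_model(sine, satp)
  expect_equal(max(M2[, "LKneeFlex"]), 0.5, tolerance = 1e-12)
  expect_equal(min(M2[, "LKneeFlex"]), -0.5, tolerance = 1e-12)
  expect_equal(unname(M2[, "LKneeFlex"]),
               pmin(pmax(sine[, "Lkneeflex"], -0.5), 0.5), tolerance = 1e-12)

  expect_error(forward_moment_model(const[, -1], moment_model_params()),
               class = "gaitssl_schema_error")
  expect_error(moment_model_params(coupling = matrix(0.05, 6, 6)),
               class = "gaitssl_invalid_argument")
})

test_that("same-joint angles are the strongest moment predictors", {
  ds <- generate_dataset(synthetic_config(n_subjects = 6,
                                          cycles_per_condition = 2,
                                          angle_noise_sd = 0, seed = 9))
  ang <- do.call(rbind, ds$cycles)
  mom <- do.call(rbind, ds$moments)
  angmap <- c("Lkneeflex", "Rkneeflex", "Lankleflex", "Rankleflex",
              "Lhipflex", "Rhipflex")
  for (j in seq_len(6)) {
    r2 <- sapply(seq_len(6), function(k)
      summary(stats::lm(mom[, j] ~ ang[, angmap[k]]))$r.squared)
    expect_equal(which.max(r2), j)
  }
})

test_that("dataset generation is deterministic and counts multiply", {
  ds <- toy_dataset(seed = 11)
  expect_equal(length(ds$cycles), 4 * 3 * 2)
  expect_true(all(vapply(ds$cycles, ncol, integer(1)) == 18))
  expect_true(all(vapply(ds$moments, nrow, integer(1)) ==
                  vapply(ds$cycles, nrow, integer(1))))
  ds2 <- toy_dataset(seed = 11)
  expect_identical(ds$cycles, ds2$cycles)
  expect_identical(ds$moments, ds2$moments)
  expect_identical(ds$digest, ds2$digest)
})

test_that("the 897-cycle total is reachable with unequal condition counts", {
  cfg <- synthetic_config(n_subjects = 55, cycles_per_condition = 5,
                          cycle_length = 20, angle_noise_sd = 0.5,
                          total_cycles = 897, seed = 2)
  ds <- generate_dataset(cfg)
  expect_equal(length(ds$cycles), 897)
})

test_that("dataset CSV round trip preserves values and alignment", {
  ds <- toy_dataset(seed = 4, n_subjects = 2, cycles = 1)
  dir <- withr::local_tempdir()
  write_gait_dataset(ds, dir)
  back <- read_gait_dataset(dir)
  expect_equal(length(back$cycles), length(ds$cycles))
  id <- names(ds$cycles)[3]
  expect_equal(unname(back$cycles[[id]]), unname(ds$cycles[[id]]),
               tolerance = 1e-10)
  expect_equal(unname(back$moments[[id]]), unname(ds$moments[[id]]),
               tolerance = 1e-10)
  expect_identical(back$digest, ds$digest)
})
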