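# Synthetic EMG generator: determinism, shapes, confound mechanics.

small_cfg <- function(...) {
  generator_config(n_subjects = 1, n_channels = 4,
                   motion_classes = c("rest", "grip", "pinch"),
                   conditions = 1:2, reps_per_condition = 2,
                   trial_duration = 0.3, ...)
}

test_that("class profiles are deterministic, distinct, and nonnegative", {
  cfg <- generator_config(n_subjects = 2)
  p1 <- make_class_profiles(cfg, 1)
  p2 <- make_class_profiles(cfg, 1)
  expect_identical(p1, p2)
  expect_equal(dim(p1$base_amplitude), c(8, 8))
  expect_true(all(p1$base_amplitude >= 0))
  d <- as.matrix(dist(p1$base_amplitude))
  expect_true(all(d[upper.tri(d)] > 0))
  expect_equal(unname(p1$base_amplitude[cfg$no_motion, ]),
               rep(cfg$noise_floor, 8))
  # another subject gets a different profile
  expect_false(identical(p1$base_amplitude,
                         make_class_profiles(cfg, 2)$base_amplitude))
  expect_error(make_class_profiles(cfg, 3), "1..n_subjects")
})

test_that("position transform degenerates to identity at alpha = 0 / reference", {
  cfg <- small_cfg(position_mixing_strength = 0, baseline_activity_level = 0.3)
  tr <- make_condition_transform(cfg, 1, 1)
  expect_equal(tr$mixing_matrix, diag(4))
  expect_equal(tr$baseline_gain, 0)   # reference position
  expect_equal(tr$gain, 1)
  cfg2 <- small_cfg(position_mixing_strength = 0.5)
  tr2 <- make_condition_transform(cfg2, 2, 1)
  expect_equal(unname(rowSums(tr2$mixing_matrix)), rep(1, 4), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(tr2$mixing_matrix, diag(4))))
  expect_error(make_condition_transform(cfg, 99, 1), "unknown condition",
               class = "emg_condition_error")
})

test_that("intensity transform follows the gain power law and peak interpolation", {
  cfg <- generator_config(n_subjects = 1, condition_kind = "intensity",
                          conditions = c(0.2, 0.5, 0.8),
                          peak_shift_range = c(10, 40))
  expect_equal(make_condition_transform(cfg, 0.2, 1)$gain, 0.2)
  expect_equal(make_condition_transform(cfg, 0.8, 1)$gain, 0.8)
  expect_equal(make_condition_transform(cfg, 0.2, 1)$spectral_peak, 10)
  expect_equal(make_condition_transform(cfg, 0.8, 1)$spectral_peak, 40)
  expect_equal(make_condition_transform(cfg, 0.5, 1)$spectral_peak, 25)
  cfg_g2 <- generator_config(n_subjects = 1, condition_kind = "intensity",
                             conditions = c(0.5, 1), intensity_gain_exponent = 2)
  expect_equal(make_condition_transform(cfg_g2, 0.5, 1)$gain, 0.25)
  expect_equal(make_condition_transform(cfg_g2, 1, 1)$gain, 1)
  # intensity leaves channels unmixed
  expect_equal(make_condition_transform(cfg, 0.5, 1)$mixing_matrix, diag(8))
})

test_that("trial synthesis is seed-deterministic and honors the silent limit", {
  cfg <- small_cfg()
  p <- make_class_profiles(cfg, 1)
  tr <- make_condition_transform(cfg, 1, 1)
  r1 <- synthesize_trial(p, tr, "grip", cfg, trial_seed = 7)
  r2 <- synthesize_trial(p, tr, "grip", cfg, trial_seed = 7)
  expect_identical(r1$data, r2$data)
  expect_equal(dim(r1$data), c(4, round(0.3 * 1000)))
  r3 <- synthesize_trial(p, tr, "grip", cfg, trial_seed = 8)
  expect_false(identical(r1$data, r3$data))

  cfg0 <- small_cfg(noise_floor = 0, position_mixing_strength = 0,
                    baseline_activity_level = 0)
  p0 <- make_class_profiles(cfg0, 1)
  tr0 <- make_condition_transform(cfg0, 1, 1)
  rest <- synthesize_trial(p0, tr0, "rest", cfg0, trial_seed = 1)
  expect_true(all(rest$data == 0))  # no-motion row is 0 when the floor is 0
  expect_error(synthesize_trial(p, tr, "jump", cfg), "unknown motion_label")
})

test_that("dataset generation is balanced, shaped, and seed-sensitive", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  expect_length(ds, 1 * 2 * 3 * 2)
  tab <- table(vapply(ds, function(r) r$motion_label, character(1)))
  expect_true(all(tab == tab[1]))  # balanced classes
  expect_true(all(vapply(ds, function(r) nrow(r$data), integer(1)) == 4))
  expect_true(all(vapply(ds, function(r) ncol(r$data), integer(1)) == 300))
  ds_b <- generate_dataset(small_cfg(seed = 2))
  expect_false(identical(ds[[1]]$data, ds_b[[1]]$data))
  # bit-exact reproducibility of the whole dataset
  expect_identical(lapply(generate_dataset(cfg), `[[`, "data"),
                   lapply(ds, `[[`, "data"))
})

test_that("mean rectified amplitude scales with the configured gain ratio", {
  cfg <- generator_config(n_subjects = 1, n_channels = 2,
                          motion_classes = c("rest", "grip"),
                          condition_kind = "intensity",
                          conditions = c(0.2, 0.8), reps_per_condition = 1,
                          trial_duration = 4, seed = 11)
  p <- make_class_profiles(cfg, 1)
  lo <- synthesize_trial(p, make_condition_transform(cfg, 0.2, 1), "grip", cfg, 5)
  hi <- synthesize_trial(p, make_condition_transform(cfg, 0.8, 1), "grip", cfg, 6)
  ws <- segment(list(lo, hi))
  mav <- rowMeans(apply(ws$windows, c(1, 2), function(x) mean(abs(x))))
  ratio <- mean(mav[ws$meta$condition_value == 0.8]) /
    mean(mav[ws$meta$condition_value == 0.2])
  expect_gt(ratio, 4 * 0.95)
  expect_lt(ratio, 4 * 1.05)
})

test_that("position remixing perturbs class amplitude patterns, alpha = 0 does not", {
  mean_pattern <- function(cfg, cond) {
    p <- make_class_profiles(cfg, 1)
    tr <- make_condition_transform(cfg, cond, 1)
    r <- synthesize_trial(p, tr, "grip", cfg, trial_seed = 3)
    rowMeans(abs(r$data))
  }
  cfg_on <- small_cfg(position_mixing_strength = 0.6,
                      baseline_activity_level = 0.3, seed = 4)
  v1 <- mean_pattern(cfg_on, 1); v2 <- mean_pattern(cfg_on, 2)
  expect_gt(sqrt(sum((v1 - v2)^2)) / sqrt(sum(v1^2)), 0)
  cfg_off <- small_cfg(position_mixing_strength = 0,
                       baseline_activity_level = 0, seed = 4)
  w1 <- mean_pattern(cfg_off, 1); w2 <- mean_pattern(cfg_off, 2)
  expect_equal(w1 / w2, rep(1, 4), tolerance = 0.1)  # same pattern up to noise
})

test_that("config validation rejects malformed studies", {
  expect_error(generator_config(condition_kind = "intensity", conditions = c(0, 0.5)),
               "strictly in")
  expect_error(generator_config(motion_classes = c("a", "b"), no_motion = "c"),
               "no-motion")
  expect_error(generator_config(conditions = numeric(0)), "nonempty")
  expect_error(generator_config(trial_duration = 0.01), "150 ms")
})
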