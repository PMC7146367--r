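# Feature catalog: hand anchors, oracle equivalence, equivariances,
# parameter recovery, and set composition.

test_that("hand-computable anchors hold", {
  expect_equal(extract_feature(c(1, -1, 2, -2), "MAV"), 1.5)
  expect_equal(extract_feature(c(0, 1, 0, 1), "WL"), 3)
  expect_equal(extract_feature(c(1, -1, 1, -1), "ZC"), 3)
  expect_equal(extract_feature(c(0, 1, 0, 1, 0), "SSC"), 3)
  expect_equal(extract_feature(c(3, 4), "RMS"), sqrt(12.5), tolerance = 1e-12)
})

test_that("every catalog feature matches its independent oracle on random windows", {
  set.seed(123)
  for (rep in 1:20) {
    x <- rnorm(sample(40:200, 1), sd = runif(1, 0.1, 2))
    for (f in names(feature_oracles)) {
      got <- extract_feature(x, f)
      want <- feature_oracles[[f]](x)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("%s (rep %d)", f, rep))
    }
  }
})

test_that("scale equivariance classes hold", {
  set.seed(7)
  x <- rnorm(120)
  for (c_ in c(0.5, 3, 10)) {
    y <- c_ * x
    for (f in c("MAV", "RMS", "IEMG", "WL", "DASDV", "MAVFD")) {
      expect_equal(extract_feature(y, f), c_ * extract_feature(x, f),
                   tolerance = 1e-9, label = paste(f, "~ c"))
    }
    for (f in c("VAR", "ACT")) {
      expect_equal(extract_feature(y, f), c_^2 * extract_feature(x, f),
                   tolerance = 1e-9, label = paste(f, "~ c^2"))
    }
    expect_equal(extract_feature(y, "MSR"), sqrt(c_) * extract_feature(x, "MSR"),
                 tolerance = 1e-9)
    expect_equal(extract_feature(y, "LS"), c_ * extract_feature(x, "LS"),
                 tolerance = 1e-9)
    for (f in c("ZC", "SSC", "MOB", "COMP")) {
      expect_equal(extract_feature(y, f, threshold = 0), extract_feature(x, f, threshold = 0),
                   tolerance = 1e-9, label = paste(f, "invariant"))
    }
  }
})

test_that("shift-invariant features ignore a constant offset", {
  set.seed(8)
  x <- rnorm(100)
  y <- x + 3.3
  for (f in c("WL", "DASDV", "MOB", "COMP", "VAR", "ACT")) {
    expect_equal(extract_feature(y, f), extract_feature(x, f), tolerance = 1e-9,
                 label = f)
  }
  # ZC on re-centered input is unchanged
  expect_equal(extract_feature(y - mean(y), "ZC"),
               extract_feature(x - mean(x), "ZC"))
})

test_that("AR4 recovers the generating coefficients of an AR(4) process", {
  set.seed(99)
  phi <- c(0.55, -0.3, 0.2, -0.1)  # stationary
  n <- 4096
  x <- as.numeric(stats::arima.sim(list(ar = phi), n = n))
  a <- extract_feature(x, "AR4")
  expect_length(a, 4)
  expect_true(all(abs(a - phi) < 0.1))
})

test_that("sample entropy is finite, nonnegative, and degenerates to zero", {
  alt <- rep(c(1, -1), 30)
  v <- extract_feature(alt, "SampEn")
  expect_true(is.finite(v))
  expect_gte(v, 0)
  set.seed(5)
  for (i in 1:10) expect_gte(extract_feature(rnorm(80), "SampEn"), 0)
  expect_equal(extract_feature(rep(2, 50), "SampEn"), 0)  # zero variance
  expect_equal(extract_feature(rep(0, 50), "MOB"), 0)
  expect_equal(extract_feature(rep(0, 50), "COMP"), 0)
})

test_that("feature sets resolve with the documented dimensionalities", {
  expect_equal(feature_set_spec("TD")$features, c("MAV", "ZC", "SSC", "WL"))
  expect_equal(feature_set_spec("TSTD")$n_per_channel, 12)
  expect_equal(feature_set_spec("Hjorth")$features, c("ACT", "MOB", "COMP"))
  cat <- list_features()
  expect_true(all(unlist(lapply(list_feature_sets(),
                                function(s) feature_set_spec(s)$features)) %in%
                    cat$name))
  expect_equal(cat$n_out[cat$name == "TDPSD"], 6L)
  expect_error(feature_set_spec("XYZ"), "unknown feature set",
               class = "emg_lookup_error")
  expect_error(extract_feature(rnorm(10), "NOPE"), "unknown feature",
               class = "emg_lookup_error")
})

test_that("extract_set lays out columns feature-major and matches extract_feature", {
  cfg <- generator_config(n_subjects = 1, n_channels = 8,
                          motion_classes = c("rest", "grip"),
                          conditions = 1:2, reps_per_condition = 2,
                          trial_duration = 0.3, seed = 3)
  ws <- segment(generate_dataset(cfg))
  td <- extract_set(ws, "TD")
  expect_equal(ncol(td$values), 4 * 8)
  expect_equal(colnames(td$values)[1:3], c("MAV[1]", "MAV[2]", "MAV[3]"))
  lsf9 <- extract_set(segment(generate_dataset(
    generator_config(n_subjects = 1, n_channels = 6,
                     motion_classes = c("rest", "grip"), conditions = 1:2,
                     reps_per_condition = 1, trial_duration = 0.3))), "LSF9")
  expect_equal(ncol(lsf9$values), 54)
  # vectorized and scalar paths agree
  w1 <- ws$windows[5, 3, ]
  expect_equal(unname(td$values[5, "MAV[3]"]), extract_feature(w1, "MAV"))
  expect_equal(unname(td$values[5, "ZC[3]"]), extract_feature(w1, "ZC"))
  expect_equal(unname(td$values[5, "WL[3]"]), extract_feature(w1, "WL"))
  # TSTD on one channel: 12 features, AR-free mix of scalar and vector paths
  cfg1 <- generator_config(n_subjects = 1, n_channels = 1,
                           motion_classes = c("rest", "grip"),
                           conditions = 1:2, reps_per_condition = 1,
                           trial_duration = 0.3)
  tstd <- extract_set(segment(generate_dataset(cfg1)), "TSTD")
  expect_equal(ncol(tstd$values), 12)
  expect_equal(nrow(tstd$values), nrow(tstd$meta))
})

test_that("TDPSD exposes the raw-descriptor mode and counts log clamps", {
  set.seed(11)
  x <- rnorm(150)
  fused <- extract_feature(x, "TDPSD")
  raw <- extract_feature(x, "TDPSD", fused = FALSE)
  expect_length(fused, 6)
  expect_length(raw, 6)
  expect_false(isTRUE(all.equal(fused, raw)))
  tdpsd_clamp_count(reset = TRUE)
  invisible(extract_feature(rep(0, 50), "TDPSD"))
  expect_gt(tdpsd_clamp_count(), 0)
})
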