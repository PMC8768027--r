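# Synthetic TOF recording generator.

test_that("simulate_twitch obeys its closed-form contract", {
  t <- seq(0, 50, by = 0.01)

  # zero amplitude -> identically zero segment
  seg0 <- simulate_twitch(t, 25, 0, 5, c(1, 0, 0))
  expect_true(all(seg0 == 0))

  # axis-aligned orientation leaves the other acceleration axes at zero
  seg <- simulate_twitch(t, 25, 2, 5, c(1, 0, 0), gyro_orientation = c(0, 1, 0))
  expect_true(all(seg[, c("ay", "az")] == 0))
  expect_equal(max(seg[, "ax"]), 2, tolerance = 1e-6)
  # peak of the combined magnitude at peak_time
  v <- sqrt(rowSums(seg[, 1:3]^2) + rowSums(seg[, 4:6]^2))
  expect_equal(t[which.max(v)], 25, tolerance = 0.5)

  # integral of the combined envelope equals A * w * c, c = sqrt((1+g^2)/6),
  # checked against numerical quadrature of the closed-form kernel
  a <- 1.7
  w <- 4.2
  g <- 0.8
  seg <- simulate_twitch(t, 25, a, w, c(0, 0, 1), gyro_scale = g)
  env <- sqrt((rowSums(seg[, 1:3]^2) + rowSums(seg[, 4:6]^2)) / 6)
  impl <- sum(env) * 0.01
  oracle <- stats::integrate(
    function(x) a * 0.5 * (1 + cos(pi * (x - 25) / w)) * sqrt((1 + g^2) / 6),
    25 - w, 25 + w
  )$value
  expect_equal(impl, oracle, tolerance = 1e-3)

  expect_error(simulate_twitch(t, 25, 1, 5, c(1, 1, 0)), "unit")
  expect_error(simulate_twitch(t, 25, -1, 5, c(1, 0, 0)), ">= 0")
  expect_error(simulate_twitch(t, 25, 1, 0, c(1, 0, 0)), "> 0")
})

test_that("normal noiseless recordings have four equal twitches and TOFR near 1", {
  cfg <- quiet_config()
  set.seed(11)
  rec <- simulate_measurement(cfg, "P01", "M001", "normal")
  f <- extract_features(rec)
  expect_equal(f$TOFR, 1, tolerance = 0.05)
  expect_equal(f$ratioT1, f$ratioT4, tolerance = 0.05 * f$ratioT1)
  amps <- c(f$T1, f$T2, f$T3, f$T4)
  expect_lt(diff(range(amps)) / mean(amps), 0.1)
})

test_that("anomaly realisations carry their defining waveform signature", {
  cfg <- generator_config(seed = 3)

  # NON_MONOTONIC_T3: the third twitch drops below both neighbours
  set.seed(21)
  for (i in 1:5) {
    rec <- simulate_measurement(cfg, "P01", sprintf("M%03d", i), "outlier",
                                anomaly_type = "NON_MONOTONIC_T3")
    f <- extract_features(rec)
    expect_lt(f$T3, f$T2)
    expect_lt(f$T3, f$T4)
  }

  # WIDE_GAP: deltaT4_T1 beyond the normal-class 99th percentile
  set.seed(22)
  normals <- purrr::map(1:300, function(i) {
    extract_features(simulate_measurement(cfg, "P01", sprintf("N%03d", i), "normal"))
  }) |> dplyr::bind_rows()
  p99 <- quantile(normals$deltaT4_T1, 0.99)
  set.seed(23)
  for (i in 1:5) {
    rec <- simulate_measurement(cfg, "P01", sprintf("W%03d", i), "outlier",
                                anomaly_type = "WIDE_GAP")
    f <- extract_features(rec)
    expect_gt(f$deltaT4_T1, p99)
  }

  # CRESCENDO: strictly increasing amplitudes
  set.seed(24)
  rec <- simulate_measurement(cfg, "P01", "C001", "outlier",
                              anomaly_type = "CRESCENDO")
  f <- extract_features(rec)
  expect_true(f$T1 < f$T4)

  expect_error(
    simulate_measurement(cfg, "P01", "X", "outlier", anomaly_type = "BOGUS"),
    "anomaly_type"
  )
  expect_error(simulate_measurement(cfg, "P01", "X", "normal",
                                    anomaly_type = "WIDE_GAP"), "absent")
  expect_error(simulate_measurement(cfg, "P01", "X", "outlier"), "anomaly_type")
})

test_that("simulate_dataset reproduces the cohort bookkeeping exactly", {
  co <- default_cohort()
  ds <- co$recordings
  expect_equal(nrow(ds), 533L)
  expect_equal(sum(ds$label == "outlier"), 30L)
  expect_equal(length(unique(ds$patient_id)), 35L)
  expect_equal(length(unique(ds$patient_id[ds$label == "outlier"])), 18L)
  expect_true(all(is.na(ds$anomaly_type) == (ds$label == "normal")))
  expect_false(anyDuplicated(ds$measurement_id) > 0)

  # no outliers requested -> all normal
  ds0 <- simulate_dataset(generator_config(
    n_patients = 4, n_measurements = 12, n_outliers = 0,
    n_outlier_patients = 0, seed = 1
  ))
  expect_true(all(ds0$label == "normal"))

  # byte-identical reproduction under the same seed
  a <- simulate_dataset(small_config(seed = 9))
  b <- simulate_dataset(small_config(seed = 9))
  expect_identical(a, b)

  expect_error(generator_config(n_outliers = 2, n_outlier_patients = 5),
               "Infeasible")
  expect_error(generator_config(n_outliers = 600), "exceed")
})

test_that("recordings respect the raw-signal invariants", {
  ds <- simulate_dataset(small_config(seed = 2))
  for (i in seq_len(nrow(ds))) {
    sig <- ds$signal[[i]]
    expect_true(all(diff(sig$t) > 0))
    expect_lt(max(abs(diff(diff(sig$t)))), 1e-9)
    expect_gte(nrow(sig), 4 * 14)
  }
})

test_that("extracted-feature marginals are calibrated to the reference", {
  co <- default_cohort()
  cr <- calibration_report(co$features)
  key <- cr[cr$feature %in% c("T1", "deltaT2_T1", "ratioT1", "AMG_Mean"), ]
  expect_true(all(abs(key$rel_dev_mean) <= 0.2))
  tofr <- cr[cr$feature == "TOFR", ]
  expect_lte(abs(tofr$obs_mean - 0.84), 0.2)

  # degenerate generator: constant amplitudes -> essentially constant TOFR
  cfg0 <- quiet_config(n_patients = 3, n_measurements = 15, n_outliers = 0,
                       n_outlier_patients = 0, seed = 5)
  ds0 <- simulate_dataset(cfg0)
  f0 <- build_feature_table(ds0)
  expect_lt(sd(f0$TOFR), 0.05)

  expect_error(calibration_report(tibble::tibble()), "non-empty")
})

test_that("amplitude matching moves the class signal into pattern features", {
  # Kolmogorov-Smirnov separation: T1 marginals overlap far more than the
  # deltaT4_T1 marginals, i.e. the engineered timing feature is the
  # informative one by construction.
  cfg <- generator_config(
    n_patients = 30, n_measurements = 300, n_outliers = 90,
    n_outlier_patients = 30, seed = 13
  )
  ds <- simulate_dataset(cfg)
  ft <- build_feature_table(ds)
  out <- ft$label == "outlier"
  ks_t1 <- suppressWarnings(
    stats::ks.test(ft$T1[out], ft$T1[!out])$statistic
  )
  ks_d41 <- suppressWarnings(
    stats::ks.test(ft$deltaT4_T1[out], ft$deltaT4_T1[!out])$statistic
  )
  expect_lt(ks_t1, ks_d41)
})
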