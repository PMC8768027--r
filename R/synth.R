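# Synthetic train-of-four recording generator.
#
# A recording is four (normally) raised-cosine acceleration bursts projected
# onto a random spatial orientation, with a phase-aligned angular-velocity
# copy and independent Gaussian sensor noise on all six channels.

raised_cosine <- function(t, peak_time, width) {
  u <- (t - peak_time) / width
  ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
}

#' Simulate a single twitch burst on six kinetic channels
#'
#' Generates one smooth unimodal muscle-contraction burst: a raised-cosine
#' envelope of the given amplitude and half-width, projected onto the three
#' acceleration axes via `orientation` and onto the angular-velocity axes via
#' a phase-aligned copy scaled by `gyro_scale` along `gyro_orientation`.
#' The burst is deterministic given its arguments; sensor noise is added at
#' the measurement level, not here.
#'
#' @param t Numeric vector of sample times (time units).
#' @param peak_time Time of the burst peak.
#' @param amplitude Peak amplitude (raw channel units), `>= 0`.
#' @param width Half-width of the raised-cosine kernel, `> 0`. The kernel
#'   integrates to `amplitude * width`.
#' @param orientation Unit 3-vector giving the spatial direction of the
#'   acceleration burst.
#' @param gyro_orientation Unit 3-vector for the angular-velocity burst;
#'   defaults to `orientation`.
#' @param gyro_scale Relative amplitude of the angular-velocity copy.
#' @return A numeric matrix with `length(t)` rows and columns
#'   `ax, ay, az, gx, gy, gz`.
#' @examples
#' seg <- simulate_twitch(0:50, peak_time = 25, amplitude = 2, width = 5,
#'                        orientation = c(1, 0, 0))
#' max(seg[, "ax"])
#' @export
simulate_twitch <- function(t, peak_time, amplitude, width, orientation,
                            gyro_orientation = orientation, gyro_scale = 1) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (width <= 0) abort("`width` must be > 0.")
  for (o in list(orientation, gyro_orientation)) {
    if (length(o) != 3L || abs(sqrt(sum(o^2)) - 1) > 1e-6) {
      abort("orientation vectors must be unit 3-vectors.")
    }
  }
  k <- amplitude * raised_cosine(t, peak_time, width)
  out <- cbind(
    outer(k, orientation),
    outer(gyro_scale * k, gyro_orientation)
  )
  colnames(out) <- c("ax", "ay", "az", "gx", "gy", "gz")
  out
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Truncated-normal draw on (lo, hi] by rejection; the acceptance region is
# wide for the default fade parameters so this terminates quickly.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > lo && x <= hi) {
      return(x)
    }
  }
}

# Draw the normal-class per-measurement kinetics: first-twitch peak amplitude
# (lognormal: the product of per-patient kinetic scale and block depth spans
# about two orders of magnitude in clinical recordings) and fade factor f
# giving amplitudes A1 * f^(i-1).
draw_normal_kinetics <- function(config) {
  sdlog <- 0.75
  a1 <- stats::rlnorm(1, meanlog = log(config$twitch_amplitude_scale) -
                        sdlog^2 / 2, sdlog = sdlog)
  f <- rtruncnorm1(
    config$fade_distribution_params$mean,
    config$fade_distribution_params$sd,
    0.05, 1.15
  )
  # per-twitch multiplicative jitter: evoked responses scatter around the
  # geometric fade rather than following it exactly
  jitter <- exp(rnorm(4, 0, config$twitch_jitter_sd))
  list(a1 = a1, fade = f, amplitudes = a1 * f^(0:3) * jitter)
}

draw_normal_intervals <- function(config, n = 3L) {
  m <- config$inter_twitch_interval_mean
  s <- config$inter_twitch_interval_sd
  vapply(seq_len(n), function(i) rtruncnorm1(m, s, m / 2, 2 * m), numeric(1))
}

# Peak schedule + amplitudes (+ optional additive oscillation) per class.
draw_measurement_plan <- function(config, label, anomaly_type) {
  lead <- runif(1, 6, 12)
  plan <- list(oscillation = NULL)
  kin <- draw_normal_kinetics(config)

  if (label == "normal") {
    plan$peak_times <- lead + cumsum(c(0, draw_normal_intervals(config)))
    plan$amplitudes <- kin$amplitudes
    return(plan)
  }

  amps <- kin$amplitudes

  switch(anomaly_type,
    REBOUND_BURST = {
      # one quick movement: four sharp sub-bursts with the inter-twitch
      # distance compressed several-fold
      iv <- draw_normal_intervals(config) / runif(1, 5, 7)
      plan$peak_times <- lead + cumsum(c(0, iv))
      plan$amplitudes <- amps * 0.85
      plan$width <- config$twitch_width * 0.3
    },
    NON_MONOTONIC_T3 = {
      plan$peak_times <- lead + cumsum(c(0, draw_normal_intervals(config)))
      amps[3] <- min(amps[2], amps[4]) * runif(1, 0.1, 0.3)
      plan$amplitudes <- amps
    },
    EQUIDISTANT_OSCILLATION = {
      n_peaks <- sample(12:16, 1)
      spacing <- config$inter_twitch_interval_mean * runif(1, 0.55, 0.8)
      plan$peak_times <- lead + spacing * (seq_len(n_peaks) - 1)
      # beat-like amplitude modulation rides on the oscillation
      mod <- ifelse(seq_len(n_peaks) %% 3 == 1, 1.08, 1)
      plan$amplitudes <- mean(amps) * mod * runif(n_peaks, 0.97, 1.03)
    },
    CRESCENDO = {
      plan$peak_times <- lead + cumsum(c(0, draw_normal_intervals(config)))
      # reverse fade inside the supra-physiological TOFR range, so the
      # ratio alone does not give the anomaly away
      g <- runif(1, 0.8, 0.92)
      plan$amplitudes <- kin$a1 * g^(3:0)
    },
    DECRESCENDO_GROSS_OSC = {
      iv <- draw_normal_intervals(config)
      factor <- runif(3, 1.8, 2.4)
      plan$peak_times <- lead + cumsum(c(0, iv * factor))
      plan$amplitudes <- amps
      plan$oscillation <- list(
        amplitude = runif(1, 0.4, 0.6) * kin$a1,
        period = runif(1, 3, 6),
        span = c(lead - config$twitch_width,
                 max(plan$peak_times) + config$twitch_width)
      )
    },
    MISSING_PEAKS = {
      plan$peak_times <- lead + cumsum(c(0, draw_normal_intervals(config)))
      # the late twitches are the ones that collapse below the noise floor
      drop <- 3:4
      amps[drop] <- 0
      plan$amplitudes <- amps
    },
    WIDE_GAP = {
      iv <- draw_normal_intervals(config)
      g <- sample(2:3, 1)
      iv[g] <- iv[g] * runif(1, 3.5, 6)
      plan$peak_times <- lead + cumsum(c(0, iv))
      plan$amplitudes <- amps
    },
    abort(sprintf("Unknown anomaly type: %s", anomaly_type))
  )

  if (config$amplitude_matched_anomalies) {
    # Recording duration scales with the envelope mass of what was recorded
    # (the app keeps recording while movement continues), so per-measurement
    # envelope statistics (AMG mean/SD) stay in the normal range and the
    # class signal sits in the waveform pattern, not in amplitude scale.
    mass_normal <- config$twitch_width * sum(kin$amplitudes)
    mass_plan <- (plan$width %||% config$twitch_width) * sum(plan$amplitudes)
    if (!is.null(plan$oscillation)) {
      mass_plan <- mass_plan +
        plan$oscillation$amplitude * diff(plan$oscillation$span) * 2 / pi
    }
    plan$length_factor <- max(0.5, min(3, mass_plan / mass_normal))
  } else {
    # Unmatched mode: anomalies additionally carry an amplitude-scale
    # artefact, so basic amplitude features become discriminative too.
    plan$amplitudes <- plan$amplitudes * runif(1, 0.3, 3)
    if (!is.null(plan$oscillation)) {
      plan$oscillation$amplitude <- plan$oscillation$amplitude * runif(1, 0.3, 3)
    }
  }
  plan
}

#' Simulate one labelled TOF recording
#'
#' Produces a single train-of-four measurement: four raised-cosine twitch
#' bursts (normal class) or a realisation of one of the seven anomaly classes
#' (see [anomaly_types()]), on six kinetic channels (triaxial acceleration and
#' angular velocity) with additive Gaussian sensor noise. Draws from the
#' current RNG state; seed at the dataset level for reproducibility.
#'
#' @param config A [generator_config()].
#' @param patient_id,measurement_id Identifiers stored with the recording.
#' @param label `"normal"` or `"outlier"`.
#' @param anomaly_type Required iff `label == "outlier"`; one of
#'   [anomaly_types()].
#' @return A one-row tibble with columns `measurement_id`, `patient_id`,
#'   `label`, `anomaly_type` and a `signal` list-column holding a tibble with
#'   columns `t, ax, ay, az, gx, gy, gz`.
#' @examples
#' set.seed(1)
#' rec <- simulate_measurement(generator_config(), "P01", "M001", "normal")
#' rec$signal[[1]]
#' @export
simulate_measurement <- function(config, patient_id, measurement_id,
                                 label = c("normal", "outlier"),
                                 anomaly_type = NULL) {
  label <- match.arg(label)
  if (label == "outlier") {
    if (is.null(anomaly_type) || !anomaly_type %in% anomaly_types()) {
      abort("Outlier recordings need an `anomaly_type` from anomaly_types().")
    }
  } else if (!is.null(anomaly_type)) {
    abort("`anomaly_type` must be absent for normal recordings.")
  }

  plan <- draw_measurement_plan(config, label, anomaly_type)
  w <- plan$width %||% config$twitch_width
  # recording duration varies between stimulations, as with a hand-held app
  target_len <- round(config$record_length * runif(1, 0.75, 1.25) *
                        (plan$length_factor %||% 1))
  n <- max(target_len, ceiling(max(plan$peak_times) + 3 * w))
  t <- seq(0, by = 1 / config$sampling_rate, length.out = n)

  orientation <- random_unit_vector()
  gyro_orientation <- random_unit_vector()
  sig <- matrix(0, nrow = n, ncol = 6,
                dimnames = list(NULL, c("ax", "ay", "az", "gx", "gy", "gz")))
  for (i in seq_along(plan$peak_times)) {
    sig <- sig + simulate_twitch(
      t, plan$peak_times[i], plan$amplitudes[i], w,
      orientation, gyro_orientation, config$gyro_scale
    )
  }
  if (!is.null(plan$oscillation)) {
    o <- plan$oscillation
    in_span <- t >= o$span[1] & t <= o$span[2]
    wave <- numeric(n)
    wave[in_span] <- o$amplitude * sin(2 * pi * (t[in_span] - o$span[1]) / o$period)
    sig <- sig + cbind(outer(wave, orientation),
                       outer(config$gyro_scale * wave, gyro_orientation))
  }
  # background tremor: low-amplitude narrowband hand movement with a
  # random per-measurement level, in the same physical direction as the
  # evoked movement
  tremor_level <- runif(1, 0, config$tremor_max) * max(plan$amplitudes)
  if (tremor_level > 0) {
    tremor <- tremor_level * (
      sin(2 * pi * t / runif(1, 2, 4) + runif(1, 0, 2 * pi)) +
        0.6 * sin(2 * pi * t / runif(1, 4, 9) + runif(1, 0, 2 * pi))
    ) / 1.6
    sig <- sig + cbind(outer(tremor, orientation),
                       outer(config$gyro_scale * tremor, gyro_orientation))
  }
  if (config$noise_sd > 0) {
    sig <- sig + matrix(rnorm(6 * n, sd = config$noise_sd), nrow = n)
  }

  tibble::tibble(
    measurement_id = measurement_id,
    patient_id = patient_id,
    label = label,
    anomaly_type = if (is.null(anomaly_type)) NA_character_ else anomaly_type,
    signal = list(tibble::as_tibble(cbind(t = t, as.data.frame(sig))))
  )
}

#' Simulate a labelled cohort of TOF recordings
#'
#' Generates the full synthetic dataset described by a [generator_config()]:
#' `n_measurements` recordings over `n_patients` patients, with exactly
#' `n_outliers` anomalies spread over exactly `n_outlier_patients` distinct
#' patients and anomaly types allocated per `anomaly_mix`. Fully reproducible
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A tibble of class `tof_recordings`, one row per measurement, with
#'   the columns documented in [simulate_measurement()].
#' @examples
#' small <- generator_config(n_patients = 4, n_measurements = 12,
#'                           n_outliers = 3, n_outlier_patients = 2, seed = 7)
#' ds <- simulate_dataset(small)
#' table(ds$label)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "tof_generator_config"))
  with_seed(config$seed, {
    patients <- sprintf("P%02d", seq_len(config$n_patients))
    # measurements per patient: as even as possible
    per_patient <- largest_remainder(
      rep(1, config$n_patients), config$n_measurements
    )
    patient_of <- rep(patients, per_patient)

    # outlier allocation: each of the n_outlier_patients carries >= 1 anomaly
    out_counts <- integer(config$n_patients)
    if (config$n_outliers > 0) {
      op <- sample(seq_len(config$n_patients), config$n_outlier_patients)
      out_counts[op] <- 1L
      extra <- config$n_outliers - config$n_outlier_patients
      while (extra > 0L) {
        cand <- op[out_counts[op] < per_patient[op]]
        pick <- cand[sample.int(length(cand), 1L)]
        out_counts[pick] <- out_counts[pick] + 1L
        extra <- extra - 1L
      }
    }

    type_counts <- largest_remainder(config$anomaly_mix, config$n_outliers)
    type_pool <- sample(rep(anomaly_types(), type_counts))

    rows <- vector("list", config$n_measurements)
    idx <- 1L
    type_idx <- 1L
    for (p in seq_len(config$n_patients)) {
      n_p <- per_patient[p]
      labels <- c(
        rep("outlier", out_counts[p]),
        rep("normal", n_p - out_counts[p])
      )
      labels <- sample(labels)
      for (j in seq_len(n_p)) {
        at <- NULL
        if (labels[j] == "outlier") {
          at <- type_pool[type_idx]
          type_idx <- type_idx + 1L
        }
        rows[[idx]] <- simulate_measurement(
          config, patients[p], sprintf("M%04d", idx), labels[j], at
        )
        idx <- idx + 1L
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("tof_recordings", class(out))
    out
  })
}

# Reference feature marginals (mean, SD) the default generator is calibrated
# against: pooled per-measurement statistics of a 533-measurement cohort on
# the combined acceleration/angulation envelope scale.
tof_reference_marginals <- function() {
  tibble::tribble(
    ~feature, ~ref_mean, ~ref_sd,
    "T1", 1.89, 1.13,
    "T2", 1.82, 1.2,
    "T3", 1.65, 1.25,
    "T4", 1.6, 1.25,
    "TOFR", 0.84, 0.4,
    "AMG_StdDev", 0.44, 0.32,
    "AMG_Mean", 0.27, 0.23,
    "deltaT2_T1", 13.99, 6.55,
    "deltaT3_T2", 14.44, 7.23,
    "deltaT4_T3", 16.3, 18.95,
    "deltaT4_T1", 44.73, 25.36,
    "ratioT1", 8.55, 3.73,
    "ratioT2", 7.57, 2.83,
    "ratioT3", 6.52, 2.76,
    "ratioT4", 6.36, 2.9
  )
}

#' Compare extracted feature marginals with the calibration reference
#'
#' Summarises a feature table (see [build_feature_table()]) against the
#' reference per-feature means and SDs the default generator emulates, and
#' reports the relative deviation of each observed mean.
#'
#' @param feature_table A feature table with the 15 waveform feature columns.
#' @return A tibble with one row per feature: observed mean/SD, reference
#'   mean/SD, and `rel_dev_mean = (obs_mean - ref_mean) / ref_mean`.
#' @export
calibration_report <- function(feature_table) {
  if (!is.data.frame(feature_table) || nrow(feature_table) == 0L) {
    abort("`feature_table` must be a non-empty feature table.")
  }
  ref <- tof_reference_marginals()
  missing <- setdiff(ref$feature, names(feature_table))
  if (length(missing)) {
    abort(sprintf("Feature table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  obs <- feature_table |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(ref$feature),
      list(mean = ~ mean(.x), sd = ~ sd(.x))
    )) |>
    tidyr::pivot_longer(
      dplyr::everything(),
      names_to = c("feature", "stat"),
      names_pattern = "(.*)_(mean|sd)$"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    dplyr::rename(obs_mean = "mean", obs_sd = "sd")
  dplyr::left_join(obs, ref, by = "feature") |>
    dplyr::mutate(rel_dev_mean = (.data$obs_mean - .data$ref_mean) / .data$ref_mean)
}
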