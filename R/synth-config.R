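#' Anomaly taxonomy for simulated train-of-four recordings
#'
#' The seven waveform anomaly classes the generator can realise:
#'
#' * `REBOUND_BURST` — a short four-peak burst after a single movement, with
#'   inter-twitch distances compressed at least three-fold.
#' * `NON_MONOTONIC_T3` — the third twitch drops below both its neighbours,
#'   breaking the monotone fade expected under non-depolarising block.
#' * `EQUIDISTANT_OSCILLATION` — six or more near-equal peaks at roughly
#'   constant spacing, with no recognisable four-twitch structure.
#' * `CRESCENDO` — strictly increasing twitch amplitudes (reverse fade).
#' * `DECRESCENDO_GROSS_OSC` — fading amplitudes but grossly perturbed
#'   inter-peak spacing with a large superimposed oscillation.
#' * `MISSING_PEAKS` — at least one twitch suppressed below the noise floor.
#' * `WIDE_GAP` — one inter-twitch interval inflated at least three-fold.
#'
#' @return Character vector of the seven anomaly type names.
#' @export
anomaly_types <- function() {
  c(
    "REBOUND_BURST", "NON_MONOTONIC_T3", "EQUIDISTANT_OSCILLATION",
    "CRESCENDO", "DECRESCENDO_GROSS_OSC", "MISSING_PEAKS", "WIDE_GAP"
  )
}

#' Configuration for the synthetic TOF recording generator
#'
#' Defines the study conditions the generator emulates: a cohort of patients
#' each contributing several train-of-four (TOF) measurements, a small number
#' of which are waveform anomalies concentrated in a subset of patients.
#' Defaults reproduce a 533-measurement, 35-patient cohort with 30 anomalies
#' spread over 18 patients, the class imbalance (~5.6% outliers) typical of
#' intraoperative acceleromyographic monitoring data.
#'
#' Time is measured in samples, one sample per centisecond. Amplitudes are in
#' combined acceleration/angulation envelope units.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_measurements Total number of TOF measurements.
#' @param n_outliers Number of anomalous measurements.
#' @param n_outlier_patients Number of distinct patients carrying anomalies.
#' @param sampling_rate Samples per time unit (1 sample = 1 centisecond).
#' @param inter_twitch_interval_mean,inter_twitch_interval_sd Mean and SD of
#'   the interval between successive twitch peaks, in time units. The default
#'   mean of 14 reproduces the inter-twitch deltas observed on the combined
#'   envelope scale.
#' @param twitch_amplitude_scale Mean peak amplitude of the first twitch, in
#'   raw channel units before envelope combination.
#' @param twitch_width Half-width of the raised-cosine twitch burst, in time
#'   units.
#' @param fade_distribution_params Named list with `mean` and `sd` of the
#'   per-measurement fade factor `f`; `f` is drawn from a normal truncated to
#'   `(0.05, 1.15]`, spanning deep block (f near 0) through supra-physiological
#'   recovery (f > 1), so the train-of-four ratio T4/T1 = f^3 covers the
#'   clinically observed range.
#' @param twitch_jitter_sd SD (log scale) of the per-twitch multiplicative
#'   amplitude jitter around the geometric fade.
#' @param tremor_max Upper bound of the per-measurement background tremor
#'   level, as a fraction of the largest twitch amplitude.
#' @param noise_sd SD of the additive Gaussian sensor noise per raw channel.
#' @param record_length Number of samples per recording (anomalies that need
#'   more room extend it).
#' @param gyro_scale Amplitude of the angular-velocity profile relative to the
#'   acceleration profile (the two are phase-aligned copies with independent
#'   noise).
#' @param anomaly_mix Named numeric vector of proportions over
#'   [anomaly_types()]; must sum to 1. Default uniform.
#' @param amplitude_matched_anomalies If `TRUE` (default), anomaly twitch
#'   amplitudes are drawn from the normal class's amplitude machinery, so
#'   amplitude-only features carry minimal class signal and the discriminative
#'   information sits in the waveform pattern.
#' @param seed Integer seed making the generated dataset fully reproducible.
#' @return A list of class `tof_generator_config`.
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$n_measurements
#' @export
generator_config <- function(n_patients = 35L,
                             n_measurements = 533L,
                             n_outliers = 30L,
                             n_outlier_patients = 18L,
                             sampling_rate = 1,
                             inter_twitch_interval_mean = 14,
                             inter_twitch_interval_sd = 2,
                             twitch_amplitude_scale = 4.8,
                             twitch_width = 5,
                             fade_distribution_params = list(mean = 0.93, sd = 0.16),
                             twitch_jitter_sd = 0.08,
                             tremor_max = 0.05,
                             noise_sd = 0.015,
                             record_length = 225L,
                             gyro_scale = 1,
                             anomaly_mix = NULL,
                             amplitude_matched_anomalies = TRUE,
                             seed = 42L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients", 1L),
    n_measurements = check_count(n_measurements, "n_measurements", 1L),
    n_outliers = check_count(n_outliers, "n_outliers", 0L),
    n_outlier_patients = check_count(n_outlier_patients, "n_outlier_patients", 0L),
    sampling_rate = check_positive(sampling_rate, "sampling_rate"),
    inter_twitch_interval_mean =
      check_positive(inter_twitch_interval_mean, "inter_twitch_interval_mean"),
    inter_twitch_interval_sd =
      check_nonneg(inter_twitch_interval_sd, "inter_twitch_interval_sd"),
    twitch_amplitude_scale =
      check_positive(twitch_amplitude_scale, "twitch_amplitude_scale"),
    twitch_width = check_positive(twitch_width, "twitch_width"),
    fade_distribution_params = fade_distribution_params,
    twitch_jitter_sd = check_nonneg(twitch_jitter_sd, "twitch_jitter_sd"),
    tremor_max = check_nonneg(tremor_max, "tremor_max"),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    record_length = check_count(record_length, "record_length", 50L),
    gyro_scale = check_nonneg(gyro_scale, "gyro_scale"),
    amplitude_matched_anomalies = isTRUE(amplitude_matched_anomalies),
    seed = check_count(abs(seed), "seed", 0L)
  )
  if (is.null(anomaly_mix)) {
    anomaly_mix <- stats::setNames(
      rep(1 / 7, 7L), anomaly_types()
    )
  }
  if (is.null(names(anomaly_mix)) ||
    !setequal(names(anomaly_mix), anomaly_types())) {
    abort("`anomaly_mix` must be named with exactly the seven anomaly types.")
  }
  if (any(anomaly_mix < 0) || abs(sum(anomaly_mix) - 1) > 1e-8) {
    abort("`anomaly_mix` proportions must be non-negative and sum to 1.")
  }
  cfg$anomaly_mix <- anomaly_mix[anomaly_types()]
  if (!is.numeric(fade_distribution_params$mean) ||
    !is.numeric(fade_distribution_params$sd)) {
    abort("`fade_distribution_params` needs numeric `mean` and `sd`.")
  }
  if (cfg$n_outliers > cfg$n_measurements) {
    abort("`n_outliers` cannot exceed `n_measurements`.")
  }
  if (cfg$n_outlier_patients > cfg$n_patients) {
    abort("`n_outlier_patients` cannot exceed `n_patients`.")
  }
  if (cfg$n_outliers > 0 && cfg$n_outliers < cfg$n_outlier_patients) {
    abort("Infeasible allocation: fewer outliers than outlier-bearing patients.")
  }
  structure(cfg, class = "tof_generator_config")
}

#' @export
print.tof_generator_config <- function(x, ...) {
  cat("<tof_generator_config>\n")
  cat(sprintf(
    "  %d measurements / %d patients; %d outliers in %d patients\n",
    x$n_measurements, x$n_patients, x$n_outliers, x$n_outlier_patients
  ))
  cat(sprintf(
    "  inter-twitch interval %.1f (sd %.1f), fade ~ TN(%.2f, %.2f), noise sd %.3f\n",
    x$inter_twitch_interval_mean, x$inter_twitch_interval_sd,
    x$fade_distribution_params$mean, x$fade_distribution_params$sd, x$noise_sd
  ))
  cat(sprintf(
    "  amplitude-matched anomalies: %s; seed %d\n",
    x$amplitude_matched_anomalies, x$seed
  ))
  invisible(x)
}
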