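# Envelope combination, twitch detection, and the 15 waveform features.

#' Names of the basic and engineered feature sets
#'
#' The 7 basic features are the integrated twitch amplitudes T1–T4, the
#' train-of-four ratio, and the mean and SD of the whole-measurement envelope.
#' The 8 engineered features capture TOF pattern shape: the four inter-twitch
#' time deltas and the four twitch-to-envelope-mean ratios.
#'
#' @return Character vector of feature column names.
#' @export
basic_features <- function() {
  c("T1", "T2", "T3", "T4", "TOFR", "AMG_StdDev", "AMG_Mean")
}

#' @rdname basic_features
#' @export
engineered_features <- function() {
  c(
    "deltaT2_T1", "deltaT3_T2", "deltaT4_T3", "deltaT4_T1",
    "ratioT1", "ratioT2", "ratioT3", "ratioT4"
  )
}

#' @rdname basic_features
#' @export
all_features <- function() c(basic_features(), engineered_features())

#' Parameters of the feature extractor
#'
#' @param gyro_weight Relative weight of the angular-velocity channels in the
#'   combined envelope (dimensionless).
#' @param min_separation Minimum distance between detected twitch peaks
#'   (time units).
#' @param threshold_k Peak threshold in envelope SDs above the envelope mean.
#' @param window_halfwidth Half-width of the amplitude-integration window
#'   around each peak (time units).
#' @param tofr_convention `"t4_over_t1"` (default, the field convention for
#'   the train-of-four ratio) or `"t1_over_t4"`.
#' @param amplitude_agg `"mean"` (default; window-length robust) or `"sum"`
#'   aggregation of envelope points in the peak vicinity.
#' @return A list of class `tof_feature_params`.
#' @export
feature_params <- function(gyro_weight = 1,
                           min_separation = 5,
                           threshold_k = 1,
                           window_halfwidth = 3,
                           tofr_convention = c("t4_over_t1", "t1_over_t4"),
                           amplitude_agg = c("mean", "sum")) {
  structure(
    list(
      gyro_weight = check_nonneg(gyro_weight, "gyro_weight"),
      min_separation = check_positive(min_separation, "min_separation"),
      threshold_k = check_nonneg(threshold_k, "threshold_k"),
      window_halfwidth = check_positive(window_halfwidth, "window_halfwidth"),
      tofr_convention = match.arg(tofr_convention),
      amplitude_agg = match.arg(amplitude_agg)
    ),
    class = "tof_feature_params"
  )
}

signal_of <- function(rec) {
  if (is.data.frame(rec) && "signal" %in% names(rec)) {
    if (nrow(rec) != 1L) abort("Expected a single recording (one row).")
    return(rec$signal[[1]])
  }
  if (is.data.frame(rec) && all(c("t", "ax") %in% names(rec))) {
    return(rec)
  }
  abort("`rec` must be a one-row recordings tibble or a signal tibble.")
}

#' Combine the six kinetic channels into one movement envelope
#'
#' Removes each channel's baseline (median subtraction, which strips gravity
#' from the accelerometer axes and any gyro bias) and computes the per-sample
#' root-mean-square across the six channels, with the angular-velocity
#' channels weighted by `gyro_weight`:
#' `v = sqrt((ax^2 + ay^2 + az^2 + w^2 (gx^2 + gy^2 + gz^2)) / 6)`.
#'
#' @param rec A one-row recordings tibble (from [simulate_dataset()] /
#'   [read_recordings()]) or a raw signal tibble with columns
#'   `t, ax, ay, az, gx, gy, gz`.
#' @param gyro_weight Weight of the angular-velocity channels.
#' @return A tibble of class `tof_envelope` with columns `t` and `v`.
#' @examples
#' set.seed(1)
#' rec <- simulate_measurement(generator_config(), "P01", "M001", "normal")
#' env <- combine_axes(rec)
#' @export
combine_axes <- function(rec, gyro_weight = 1) {
  sig <- signal_of(rec)
  if (nrow(sig) == 0L) abort("Empty recording.")
  acc <- as.matrix(sig[, c("ax", "ay", "az")])
  gyr <- as.matrix(sig[, c("gx", "gy", "gz")])
  acc <- sweep(acc, 2, apply(acc, 2, median))
  gyr <- sweep(gyr, 2, apply(gyr, 2, median))
  v <- sqrt((rowSums(acc^2) + gyro_weight^2 * rowSums(gyr^2)) / 6)
  out <- tibble::tibble(t = sig$t, v = v)
  class(out) <- c("tof_envelope", class(out))
  out
}

# Indices of strict-left / weak-right local maxima of v.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# Greedy tallest-first selection of candidate indices at least `min_sep_n`
# samples apart.
select_separated <- function(idx, heights, min_sep_n) {
  keep <- integer(0)
  for (i in idx[order(-heights)]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep_n)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect the four TOF twitches on a combined envelope
#'
#' Finds local maxima of the envelope above `mean(v) + threshold_k * sd(v)`,
#' separated by at least `min_separation`, and keeps the four largest
#' (re-ordered in time). If fewer than four qualify, the threshold is relaxed
#' stepwise to zero; if the signal still offers fewer than four separated
#' maxima, the set is padded with the largest remaining non-adjacent samples
#' and `detection_quality` is flagged `"padded"`. Each twitch gets a
#' half-open integration window `[peak - window_halfwidth,
#' peak + window_halfwidth)` clipped to the signal.
#'
#' @param env A `tof_envelope` from [combine_axes()].
#' @param params A [feature_params()].
#' @return A list of class `tof_twitchset`: `peaks` (tibble with `peak_time`,
#'   `peak_index` (0-based), `amplitude`, `window_start`, `window_end`
#'   (0-based, half-open)), `n_raw_peaks_detected`, `detection_quality`.
#' @export
detect_twitches <- function(env, params = feature_params()) {
  v <- env$v
  t <- env$t
  n <- length(v)
  dt <- if (n > 1) t[2] - t[1] else 1
  min_sep_n <- max(1L, round(params$min_separation / dt))
  if (n < 4L * min_sep_n) {
    abort(sprintf(
      "Degenerate input: envelope of %d samples is shorter than 4 x min_separation.",
      n
    ))
  }

  cand <- local_maxima(v)
  quality <- "complete"
  sel <- integer(0)
  for (k in c(params$threshold_k, params$threshold_k / 2, 0)) {
    thr <- mean(v) + k * sd(v)
    above <- cand[v[cand] >= thr]
    sel <- select_separated(above, v[above], min_sep_n)
    if (length(sel) >= 4L) break
  }
  n_raw <- length(sel)
  if (length(sel) > 4L) {
    sel <- sort(sel[order(-v[sel])][1:4])
  } else if (length(sel) < 4L) {
    quality <- "padded"
    pool <- setdiff(seq_len(n), unlist(lapply(sel, function(i) {
      max(1L, i - min_sep_n + 1L):min(n, i + min_sep_n - 1L)
    })))
    for (i in pool[order(-v[pool])]) {
      if (length(sel) == 4L) break
      if (!length(sel) || all(abs(sel - i) >= min_sep_n)) sel <- sort(c(sel, i))
    }
    if (length(sel) < 4L) {
      abort("Degenerate input: could not locate four separated peaks.")
    }
  }

  hw_n <- round(params$window_halfwidth / dt)
  peaks <- tibble::tibble(
    peak_time = t[sel],
    peak_index = sel - 1L,
    window_start = pmax(sel - hw_n, 1L) - 1L,
    window_end = pmin(sel + hw_n + 1L, n + 1L) - 1L
  )
  peaks$amplitude <- vapply(
    seq_len(4L),
    function(i) twitch_amplitude(env, c(peaks$window_start[i], peaks$window_end[i]),
                                 agg = params$amplitude_agg),
    numeric(1)
  )
  structure(
    list(peaks = peaks, n_raw_peaks_detected = n_raw,
         detection_quality = quality),
    class = "tof_twitchset"
  )
}

#' Integrated amplitude of one twitch window
#'
#' Aggregates the envelope over a half-open window `[start, end)` of 0-based
#' sample indices: the arithmetic mean of the envelope points in the vicinity
#' of the peak (default), or their sum.
#'
#' @param env A `tof_envelope`.
#' @param window Integer vector `c(start, end)` of 0-based sample indices,
#'   half-open.
#' @param agg `"mean"` or `"sum"`.
#' @return A single non-negative envelope value.
#' @export
twitch_amplitude <- function(env, window, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  start <- window[1] + 1L
  end <- window[2]
  if (end <= window[1]) abort("Empty twitch window.")
  if (start < 1L || end > nrow(env)) abort("Twitch window out of signal bounds.")
  x <- env$v[start:end]
  if (agg == "mean") mean(x) else sum(x)
}

#' Extract the 15 waveform features from one recording
#'
#' Runs envelope combination and twitch detection, then computes the basic
#' features (T1–T4 integrated amplitudes, train-of-four ratio, whole-envelope
#' mean and SD) and the engineered pattern features (successive peak-time
#' deltas plus the T4–T1 span, and each twitch's ratio to the envelope mean).
#'
#' @param rec A one-row recordings tibble or raw signal tibble.
#' @param params A [feature_params()].
#' @return A one-row tibble: the 15 feature columns in canonical order,
#'   `detection_quality`, plus `label`, `measurement_id`, `patient_id` when
#'   present on the input.
#' @examples
#' set.seed(1)
#' rec <- simulate_measurement(generator_config(), "P01", "M001", "normal")
#' extract_features(rec)
#' @export
extract_features <- function(rec, params = feature_params()) {
  env <- combine_axes(rec, gyro_weight = params$gyro_weight)
  tw <- detect_twitches(env, params)
  pk <- tw$peaks
  amps <- pk$amplitude
  amg_mean <- mean(env$v)
  amg_sd <- sd(env$v)

  t1 <- amps[1]
  t4 <- amps[4]
  tofr <- if (params$tofr_convention == "t4_over_t1") {
    if (t1 == 0) {
      warn("T1 is zero; TOFR set to 0.")
      0
    } else {
      t4 / t1
    }
  } else {
    if (t4 == 0) {
      warn("T4 is zero; TOFR set to 0.")
      0
    } else {
      t1 / t4
    }
  }
  deltas <- diff(pk$peak_time)

  out <- tibble::tibble(
    T1 = amps[1], T2 = amps[2], T3 = amps[3], T4 = amps[4],
    TOFR = tofr,
    AMG_StdDev = amg_sd,
    AMG_Mean = amg_mean,
    deltaT2_T1 = deltas[1],
    deltaT3_T2 = deltas[2],
    deltaT4_T3 = deltas[3],
    deltaT4_T1 = deltas[1] + deltas[2] + deltas[3],
    ratioT1 = amps[1] / amg_mean,
    ratioT2 = amps[2] / amg_mean,
    ratioT3 = amps[3] / amg_mean,
    ratioT4 = amps[4] / amg_mean,
    detection_quality = tw$detection_quality
  )
  if (is.data.frame(rec) && "label" %in% names(rec)) {
    out$label <- rec$label
  }
  if (is.data.frame(rec) && "measurement_id" %in% names(rec)) {
    out$measurement_id <- rec$measurement_id
    out$patient_id <- rec$patient_id
  }
  out
}

#' Build the feature table for a set of recordings
#'
#' Applies [extract_features()] to every recording and binds the rows into
#' one table, one row per measurement, with the 15 feature columns in
#' canonical order followed by `label` and identifiers.
#'
#' @param recordings A `tof_recordings` tibble (one row per measurement).
#' @param params A [feature_params()].
#' @return A tibble of class `tof_features`.
#' @export
build_feature_table <- function(recordings, params = feature_params()) {
  if (!is.data.frame(recordings) || nrow(recordings) == 0L) {
    abort("`recordings` must be a non-empty recordings tibble.")
  }
  if (anyDuplicated(recordings$measurement_id)) {
    abort("Duplicate measurement_id in recordings.")
  }
  out <- purrr::map(seq_len(nrow(recordings)), function(i) {
    row <- recordings[i, ]
    tryCatch(
      extract_features(row, params),
      error = function(e) {
        abort(sprintf(
          "Feature extraction failed for measurement %s: %s",
          row$measurement_id, conditionMessage(e)
        ))
      }
    )
  }) |>
    dplyr::bind_rows()
  keep <- c(all_features(), "detection_quality",
            intersect(c("label", "measurement_id", "patient_id"), names(out)))
  out <- out[, keep]
  class(out) <- c("tof_features", class(out))
  out
}
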