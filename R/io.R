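# Plain-text I/O for recordings and feature tables.
#
# Recordings: JSON-lines (one recording per line) or long CSV (one sample per
# row). Feature tables: CSV with a fixed column order and full-precision
# decimal encoding so a write/read round trip is bit-identical.

feature_table_columns <- function(extra = character(0)) {
  c(all_features(), extra, "label", "measurement_id", "patient_id")
}

#' Write / read TOF recordings
#'
#' JSON-lines format: one JSON object per line with keys `measurement_id`,
#' `patient_id`, `label`, `anomaly_type`, and arrays `t, ax, ay, az, gx, gy,
#' gz`. CSV format: long table with one sample per row (`measurement_id,
#' patient_id, t, ax, ay, az, gx, gy, gz, label, anomaly_type`). Both encode
#' doubles at full precision and round-trip losslessly.
#'
#' @param recordings A `tof_recordings` tibble.
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `write_recordings()` returns `path` invisibly; `read_recordings()`
#'   returns a `tof_recordings` tibble.
#' @export
write_recordings <- function(recordings, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(recordings), "signal" %in% names(recordings))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(recordings)), function(i) {
      sig <- recordings$signal[[i]]
      jsonlite::toJSON(
        list(
          measurement_id = recordings$measurement_id[i],
          patient_id = recordings$patient_id[i],
          label = recordings$label[i],
          anomaly_type = recordings$anomaly_type[i],
          t = sig$t, ax = sig$ax, ay = sig$ay, az = sig$az,
          gx = sig$gx, gy = sig$gy, gz = sig$gz
        ),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
    }, character(1))
    writeLines(lines, path)
  } else {
    long <- purrr::map(seq_len(nrow(recordings)), function(i) {
      sig <- recordings$signal[[i]]
      tibble::tibble(
        measurement_id = recordings$measurement_id[i],
        patient_id = recordings$patient_id[i],
        sig,
        label = recordings$label[i],
        anomaly_type = recordings$anomaly_type[i]
      )
    }) |> dplyr::bind_rows()
    num <- vapply(long, is.numeric, logical(1))
    long[num] <- lapply(long[num], function(x) sprintf("%.17g", x))
    utils::write.csv(long, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

validate_recording <- function(rec, where) {
  sig <- rec$signal[[1]]
  lens <- vapply(sig, length, integer(1))
  if (length(unique(lens)) != 1L) {
    abort(sprintf("%s: channels have unequal lengths.", where))
  }
  if (nrow(sig) >= 2L) {
    dt <- diff(sig$t)
    if (any(dt <= 0)) abort(sprintf("%s: time not strictly increasing.", where))
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      abort(sprintf("%s: non-uniform sample spacing.", where))
    }
  }
  if (!rec$label %in% c("normal", "outlier")) {
    abort(sprintf("%s: label must be 'normal' or 'outlier'.", where))
  }
  if ((rec$label == "outlier") != !is.na(rec$anomaly_type)) {
    abort(sprintf("%s: anomaly_type must be present iff label is 'outlier'.",
                  where))
  }
  rec
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "jsonl") {
    lines <- readLines(path)
    rows <- purrr::map(seq_along(lines), function(i) {
      obj <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
        error = function(e) {
          abort(sprintf("Malformed record at line %d of %s: %s",
                        i, path, conditionMessage(e)))
        }
      )
      need <- c("measurement_id", "patient_id", "label",
                "t", "ax", "ay", "az", "gx", "gy", "gz")
      miss <- setdiff(need, names(obj))
      if (length(miss)) {
        abort(sprintf("Line %d of %s lacks fields: %s",
                      i, path, paste(miss, collapse = ", ")))
      }
      rec <- tibble::tibble(
        measurement_id = obj$measurement_id,
        patient_id = obj$patient_id,
        label = obj$label,
        anomaly_type = if (is.null(obj$anomaly_type)) NA_character_ else obj$anomaly_type,
        signal = list(tibble::tibble(
          t = obj$t, ax = obj$ax, ay = obj$ay, az = obj$az,
          gx = obj$gx, gy = obj$gy, gz = obj$gz
        ))
      )
      validate_recording(rec, sprintf("Line %d of %s", i, path))
    })
    out <- dplyr::bind_rows(rows)
  } else {
    long <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(measurement_id = "character",
                                           patient_id = "character"))
    long$anomaly_type[long$anomaly_type %in% c("", NA)] <- NA_character_
    ids <- unique(long$measurement_id)
    rows <- purrr::map(ids, function(id) {
      d <- long[long$measurement_id == id, ]
      rec <- tibble::tibble(
        measurement_id = id,
        patient_id = d$patient_id[1],
        label = d$label[1],
        anomaly_type = d$anomaly_type[1],
        signal = list(tibble::tibble(
          t = d$t, ax = d$ax, ay = d$ay, az = d$az,
          gx = d$gx, gy = d$gy, gz = d$gz
        ))
      )
      validate_recording(rec, sprintf("Measurement %s in %s", id, path))
    })
    out <- dplyr::bind_rows(rows)
  }
  class(out) <- c("tof_recordings", class(out))
  out
}

#' Write / read a feature table as CSV
#'
#' Columns are written in the canonical order (the 15 features, then label
#' and identifiers); doubles use 17-significant-digit decimal encoding so the
#' round trip reproduces bit-identical values. Unknown extra columns are
#' preserved with a warning on read.
#'
#' @param features A feature table.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a `tof_features` tibble.
#' @export
write_feature_table <- function(features, path) {
  miss <- setdiff(c(all_features(), "label"), names(features))
  if (length(miss)) {
    abort(sprintf("Feature table lacks columns: %s", paste(miss, collapse = ", ")))
  }
  known <- feature_table_columns(
    extra = intersect("detection_quality", names(features))
  )
  cols <- c(intersect(known, names(features)), setdiff(names(features), known))
  out <- features[, cols]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(all_features(), "label"), names(d))
  if (length(miss)) {
    abort(sprintf("Schema error: %s lacks columns %s",
                  path, paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(d), feature_table_columns(extra = "detection_quality"))
  if (length(extra)) {
    warn(sprintf("Preserving unknown columns: %s", paste(extra, collapse = ", ")))
  }
  for (f in all_features()) d[[f]] <- as.numeric(d[[f]])
  out <- tibble::as_tibble(d)
  class(out) <- c("tof_features", class(out))
  out
}
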