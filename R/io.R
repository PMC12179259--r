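# Readers and writers for every tabular artifact the pipeline touches.
# All files are plain comma-separated UTF-8 with a header row and "."
# decimals. Readers validate their schema strictly, never reorder rows,
# and report row drops; writers round-trip values to at least 1e-6.

#' Column mapping and unit flags for raw IMU CSV files
#'
#' Describes how the columns of an on-disk IMU export map onto the
#' canonical channels `t, ax, ay, az, gx, gy, gz`, and in which units the
#' device reports them. Internal canonical units are g for acceleration
#' and deg/s for angular velocity (the unit the comparator ENMO equations
#' are defined in); Android-convention exports in m/s^2 and rad/s are
#' converted at read time.
#'
#' @param columns Named character vector mapping canonical names to file
#'   header names.
#' @param accel_unit `"g"` or `"ms2"` (metres per second squared).
#' @param gyro_unit `"degs"` or `"rads"` (radians per second).
#' @return A list of class `imu_schema`.
#' @export
#' @examples
#' imu_schema(accel_unit = "ms2", gyro_unit = "rads")
imu_schema <- function(columns = c(t = "t", ax = "ax", ay = "ay", az = "az",
                                   gx = "gx", gy = "gy", gz = "gz"),
                       accel_unit = c("g", "ms2"),
                       gyro_unit = c("degs", "rads")) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  need <- c("t", WM_CHANNELS)
  if (!all(need %in% names(columns)))
    wm_config_error(sprintf("imu_schema is missing mappings for: %s",
                            paste(setdiff(need, names(columns)), collapse = ", ")))
  structure(list(columns = columns, accel_unit = accel_unit,
                 gyro_unit = gyro_unit),
            class = "imu_schema")
}

#' Construct a validated IMU recording
#'
#' A 6-axis inertial stream for one participant: a data frame with columns
#' `t` (seconds from stream start, strictly increasing), `ax, ay, az`
#' (acceleration, g) and `gx, gy, gz` (angular velocity, deg/s), plus
#' participant id, handedness and the nominal sampling rate as attributes.
#'
#' @param data Data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param participant_id Participant identifier string.
#' @param handedness `"left"` or `"right"` -- the wrist the watch was worn on.
#' @param sampling_rate Nominal sampling rate in Hz (default 20).
#' @return A data frame of class `imu_recording`.
#' @export
imu_recording <- function(data, participant_id, handedness = c("right", "left"),
                          sampling_rate = 20) {
  handedness <- match.arg(handedness)
  need <- c("t", WM_CHANNELS)
  miss <- setdiff(need, names(data))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    wm_contract_error("sampling_rate must be a positive number")
  data <- as.data.frame(data)[need]
  if (nrow(data) > 1L) {
    bad <- which(diff(data$t) <= 0)
    if (length(bad))
      wm_data_error(sprintf("timestamps not strictly increasing at row %d",
                            bad[[1L]] + 1L))
  }
  structure(data,
            participant_id = as.character(participant_id),
            handedness = handedness,
            sampling_rate = sampling_rate,
            class = c("imu_recording", "data.frame"))
}

#' Read a raw IMU CSV file
#'
#' Rows containing any non-finite channel value are dropped (a warning
#' reports the count); remaining timestamps must be strictly increasing.
#' Timestamps are re-based to seconds from stream start; the original
#' first timestamp is kept in attribute `t0`.
#'
#' @param path CSV file path.
#' @param schema An [imu_schema()] describing column names and units.
#' @param participant_id,handedness,sampling_rate Recording metadata (not
#'   part of the file format).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, schema = imu_schema(), participant_id = "P1",
                         handedness = "right", sampling_rate = 20) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path, check.names = FALSE)
  for (canon in c("t", WM_CHANNELS)) {
    col <- schema$columns[[canon]]
    if (!col %in% names(raw))
      wm_schema_error(sprintf("missing required column '%s'", col))
  }
  df <- data.frame(lapply(c(t = "t", stats::setNames(WM_CHANNELS, WM_CHANNELS)),
                          function(canon) as.numeric(raw[[schema$columns[[canon]]]])))
  names(df) <- c("t", WM_CHANNELS)
  keep <- rowSums(!is.finite(as.matrix(df))) == 0L
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(sprintf("dropped %d row(s) with non-finite values", n_drop),
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) wm_data_error("no rows")
  if (schema$accel_unit == "ms2")
    df[WM_ACCEL] <- df[WM_ACCEL] / 9.80665
  if (schema$gyro_unit == "rads")
    df[c("gx", "gy", "gz")] <- df[c("gx", "gy", "gz")] * (180 / pi)
  t0 <- df$t[[1L]]
  df$t <- df$t - t0
  rownames(df) <- NULL
  rec <- imu_recording(df, participant_id, handedness, sampling_rate)
  attr(rec, "t0") <- t0
  attr(rec, "n_dropped") <- n_drop
  rec
}

#' Write an IMU recording to CSV
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  write.csv(as.data.frame(unclass(rec)[c("t", WM_CHANNELS)]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a breath-by-breath calorimetry CSV
#'
#' Expected columns: `t` (seconds), `vo2` and `vco2` (litres/min).
#' Negative gas values are rejected.
#'
#' @param path CSV file path.
#' @return A data frame of class `calorimetry_trace`.
#' @export
read_calorimetry_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  miss <- setdiff(c("t", "vo2", "vco2"), names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  if (nrow(raw) == 0L) wm_data_error("no rows")
  calorimetry_trace(raw$t, raw$vo2, raw$vco2)
}

#' Construct a validated calorimetry trace
#' @param t Breath times, seconds, non-decreasing.
#' @param vo2,vco2 Oxygen uptake and carbon-dioxide production, L/min,
#'   non-negative.
#' @return A data frame of class `calorimetry_trace`.
#' @export
calorimetry_trace <- function(t, vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    wm_data_error("negative VO2/VCO2 value")
  if (length(t) > 1L && any(diff(t) < 0))
    wm_data_error("calorimetry timestamps not monotone")
  structure(data.frame(t = t, vo2 = vo2, vco2 = vco2),
            class = c("calorimetry_trace", "data.frame"))
}

#' Write a calorimetry trace to CSV
#' @param trace A `calorimetry_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calorimetry_csv <- function(trace, path) {
  write.csv(as.data.frame(unclass(trace)[c("t", "vo2", "vco2")]), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant demographics CSV
#'
#' Expected columns: `participant_id, age, sex, height_cm, weight_kg` and
#' optionally `bmi`. BMI is derived from height and weight when absent; a
#' supplied BMI inconsistent with height/weight by more than 0.5 kg/m^2 is
#' rejected.
#'
#' @param path CSV file path.
#' @return A data frame of class `demographics`.
#' @export
read_demographics_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  need <- c("participant_id", "age", "sex", "height_cm", "weight_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  demographics(raw$participant_id, raw$age, raw$sex, raw$height_cm,
               raw$weight_kg, bmi = if ("bmi" %in% names(raw)) raw$bmi)
}

#' Construct a validated demographics table
#' @param participant_id Identifier per row.
#' @param age Years.
#' @param sex `"female"` or `"male"`.
#' @param height_cm Standing height, cm.
#' @param weight_kg Body mass, kg.
#' @param bmi kg/m^2; derived from height and weight when `NULL`.
#' @return A data frame of class `demographics`.
#' @export
demographics <- function(participant_id, age, sex, height_cm, weight_kg,
                         bmi = NULL) {
  sex <- as.character(sex)
  if (!all(sex %in% c("female", "male")))
    wm_data_error("sex must be 'female' or 'male'")
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    wm_data_error("height and weight must be positive")
  derived <- weight_kg / (height_cm / 100)^2
  if (is.null(bmi)) {
    bmi <- derived
  } else if (any(abs(bmi - derived) > 0.5, na.rm = TRUE)) {
    wm_data_error("bmi inconsistent with height/weight by more than 0.5")
  }
  structure(data.frame(participant_id = as.character(participant_id),
                       age = age, sex = sex, height_cm = height_cm,
                       weight_kg = weight_kg, bmi = bmi),
            class = c("demographics", "data.frame"))
}

#' Write a demographics table to CSV
#' @param demo A `demographics` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_demographics_csv <- function(demo, path) {
  write.csv(as.data.frame(unclass(demo)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read an activity annotation CSV
#'
#' Expected columns: `label, intensity, start_s, end_s`. Intervals must be
#' well-formed (`start < end`) and non-overlapping.
#'
#' @param path CSV file path.
#' @return A data frame of class `activity_annotations`.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  miss <- setdiff(c("label", "intensity", "start_s", "end_s"), names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  activity_annotations(raw$label, raw$intensity, raw$start_s, raw$end_s)
}

#' Construct validated activity annotations
#' @param label Activity name per interval.
#' @param intensity One of `"sedentary", "light", "moderate", "vigorous"`.
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`,
#'   non-overlapping.
#' @return A data frame of class `activity_annotations`.
#' @export
activity_annotations <- function(label, intensity, start_s, end_s) {
  intensity <- as.character(intensity)
  ok <- c("sedentary", "light", "moderate", "vigorous")
  if (!all(intensity %in% ok))
    wm_data_error(sprintf("intensity must be one of: %s",
                          paste(ok, collapse = ", ")))
  if (any(start_s >= end_s))
    wm_data_error("annotation with start >= end")
  o <- order(start_s)
  if (length(start_s) > 1L && any(start_s[o][-1L] < end_s[o][-length(o)]))
    wm_data_error("overlapping annotation intervals")
  structure(data.frame(label = as.character(label), intensity = intensity,
                       start_s = start_s, end_s = end_s),
            class = c("activity_annotations", "data.frame"))
}

#' Write activity annotations to CSV
#' @param ann An `activity_annotations` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(ann, path) {
  write.csv(as.data.frame(unclass(ann)), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read an epoch-level activity-count CSV (ActiLife-style export)
#'
#' Expected columns: `epoch_start, epoch_length, counts_x, counts_y,
#' counts_z` and optionally `vector_magnitude` (derived, and checked
#' against `sqrt(cx^2 + cy^2 + cz^2)` within rounding, when present).
#'
#' @param path CSV file path.
#' @return A data frame of class `epoch_counts`.
#' @export
read_epoch_counts_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  need <- c("epoch_start", "epoch_length", "counts_x", "counts_y", "counts_z")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  if (nrow(raw) == 0L) wm_data_error("no rows")
  vm <- sqrt(raw$counts_x^2 + raw$counts_y^2 + raw$counts_z^2)
  if ("vector_magnitude" %in% names(raw)) {
    if (any(abs(raw$vector_magnitude - vm) > 1, na.rm = TRUE))
      wm_data_error("vector_magnitude inconsistent with axis counts")
    vm <- raw$vector_magnitude
  }
  structure(data.frame(raw[need], vector_magnitude = vm),
            class = c("epoch_counts", "data.frame"))
}

#' Write per-window MET predictions to CSV
#'
#' Columns: `participant_id, window_start, window_end, window_size_s,
#' stage1_label, met_pred`. With zero windows a header-only file is
#' written. Values survive a write/read round trip to 1e-6.
#'
#' @param windows A [window_set()].
#' @param met_pred Numeric MET prediction, one per window.
#' @param path Output file path.
#' @param stage1_label Optional character stage-1 label per window
#'   (`"sedentary"`/`"non-sedentary"`); defaults to `NA`.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(windows, met_pred, path, stage1_label = NULL) {
  n <- length(windows$windows)
  if (length(met_pred) != n)
    wm_contract_error(sprintf("met_pred has length %d but there are %d windows",
                              length(met_pred), n))
  if (is.null(stage1_label)) stage1_label <- rep(NA_character_, n)
  if (length(stage1_label) != n)
    wm_contract_error("stage1_label must have one entry per window")
  meta <- as.data.frame(windows)
  df <- data.frame(participant_id = meta$participant_id %||% character(0),
                   window_start = meta$start %||% numeric(0),
                   window_end = meta$end %||% numeric(0),
                   window_size_s = meta$size %||% numeric(0),
                   stage1_label = stage1_label,
                   met_pred = met_pred)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-window MET prediction CSV
#' @param path CSV file path written by [write_predictions_csv()].
#' @return A data frame with one row per window.
#' @export
read_predictions_csv <- function(path) {
  if (!file.exists(path)) wm_data_error(sprintf("file not found: %s", path))
  raw <- read.csv(path)
  need <- c("participant_id", "window_start", "window_end", "window_size_s",
            "stage1_label", "met_pred")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    wm_schema_error(sprintf("missing required column '%s'", miss[[1L]]))
  raw
}
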