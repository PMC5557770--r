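#' Sensor locations used throughout the package
#'
#' The three body-worn inertial sensors: one above each ankle and one on the
#' lower back. All recordings must carry exactly these three streams.
#'
#' @return Character vector of the three canonical location tokens.
#' @export
sensor_locations <- function() c("left_ankle", "right_ankle", "lower_back")

.loc_codes <- c(left_ankle = "la", right_ankle = "ra", lower_back = "lb")
.axis_names <- c("ap", "ml", "v")

#' Sampling configuration
#'
#' Sampling rate and analysis window length. The window length in samples is
#' `round(rate_hz * window_s)` and must span at least two samples.
#'
#' @param rate_hz Sampling frequency in samples per second. Default 128.
#' @param window_s Analysis window length in seconds. Default 2.
#' @return A `sampling_config` object with fields `rate_hz`, `window_s` and
#'   the derived `window_samples`.
#' @examples
#' sampling_config()           # 128 Hz, 2 s -> 256-sample windows
#' sampling_config(100, 2.5)
#' @export
sampling_config <- function(rate_hz = 128, window_s = 2) {
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, is.finite(rate_hz),
            rate_hz > 0,
            is.numeric(window_s), length(window_s) == 1L, is.finite(window_s),
            window_s > 0)
  ws <- as.integer(round(rate_hz * window_s))
  if (ws < 2L)
    stop("analysis window must span at least 2 samples (got ", ws, ")")
  structure(list(rate_hz = rate_hz, window_s = window_s, window_samples = ws),
            class = "sampling_config")
}

#' @export
print.sampling_config <- function(x, ...) {
  cat(sprintf("<sampling_config> %g Hz, %g s windows (%d samples)\n",
              x$rate_hz, x$window_s, x$window_samples))
  invisible(x)
}

#' Convert a time in seconds to a 0-based sample index
#'
#' All internal bookkeeping uses 0-based, half-open sample intervals; times in
#' seconds appear only at I/O boundaries. Conversion is by `floor(t * rate)`,
#' which is deterministic and never pulls a post-onset sample into an interval
#' ending at `t`.
#'
#' @param t_s Time(s) in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @return Integer 0-based sample index (vectorized).
#' @export
time_to_index <- function(t_s, rate_hz) {
  as.integer(floor(t_s * rate_hz + 1e-9))
}

#' Construct a single-sensor stream
#'
#' A synchronized pair of tri-axial acceleration (m/s^2) and angular-velocity
#' (rad/s) sample matrices from one sensor location. Axis order is
#' anteroposterior (ap), mediolateral (ml), vertical (v).
#'
#' @param location One of [sensor_locations()].
#' @param acc Numeric n x 3 matrix of acceleration samples (m/s^2).
#' @param gyro Numeric n x 3 matrix of angular velocity samples (rad/s).
#' @return A `sensor_stream` object.
#' @export
sensor_stream <- function(location, acc, gyro) {
  location <- match.arg(location, sensor_locations())
  acc <- .as_axis_matrix(acc, sprintf("%s acc", location))
  gyro <- .as_axis_matrix(gyro, sprintf("%s gyro", location))
  if (nrow(acc) != nrow(gyro))
    stop(sprintf("%s: acc has %d samples but gyro has %d",
                 location, nrow(acc), nrow(gyro)))
  structure(list(location = location, acc = acc, gyro = gyro,
                 n_samples = nrow(acc)),
            class = "sensor_stream")
}

.as_axis_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L)
    stop(what, ": expected 3 axis columns (ap, ml, v), got ", ncol(m))
  if (!is.numeric(m)) stop(what, ": values must be numeric")
  bad <- which(!is.finite(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("%s: non-finite value at row %d, axis %s",
                 what, rc[1L], .axis_names[rc[2L]]))
  }
  colnames(m) <- .axis_names
  m
}

#' Construct a recording for one subject and condition
#'
#' Bundles the three synchronized sensor streams with subject/condition
#' identifiers, the sampling configuration, and the still calibration
#' interval (a known motionless period near the start of the protocol, used
#' to estimate the resting acceleration-norm reference).
#'
#' @param subject_id,condition_id Identifier tokens.
#' @param streams List of three [sensor_stream()] objects, one per location.
#' @param sampling A [sampling_config()].
#' @param still_interval Numeric `(start_s, end_s)` of the motionless
#'   calibration period; must lie within the recording and span at least 1 s.
#' @return A `recording` object.
#' @export
recording <- function(subject_id, condition_id, streams,
                      sampling = sampling_config(),
                      still_interval) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            nzchar(subject_id),
            is.character(condition_id), length(condition_id) == 1L,
            inherits(sampling, "sampling_config"))
  if (!is.list(streams)) stop("streams must be a list of sensor_stream")
  locs <- vapply(streams, function(s) s$location, character(1))
  names(streams) <- locs
  missing <- setdiff(sensor_locations(), locs)
  if (length(missing))
    stop("missing sensor location(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(locs)) stop("duplicated sensor location")
  streams <- streams[sensor_locations()]
  ns <- vapply(streams, function(s) s$n_samples, integer(1))
  if (length(unique(ns)) != 1L)
    stop("streams have unequal lengths: ",
         paste(sprintf("%s=%d", names(ns), ns), collapse = ", "))
  dur <- ns[[1L]] / sampling$rate_hz
  still_interval <- as.numeric(still_interval)
  stopifnot(length(still_interval) == 2L, all(is.finite(still_interval)))
  if (still_interval[1L] < 0 || still_interval[2L] > dur + 1e-9 ||
      diff(still_interval) < 1 - 1e-9)
    stop(sprintf(
      "still_interval [%g, %g] must lie within the %.3f s recording and span >= 1 s",
      still_interval[1L], still_interval[2L], dur))
  structure(list(subject_id = subject_id, condition_id = condition_id,
                 sampling = sampling, streams = streams,
                 still_interval = still_interval),
            class = "recording")
}

#' Number of samples in a recording
#' @param rec A [recording()].
#' @return Integer sample count (shared by all three streams).
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$streams[[1L]]$n_samples
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) n_samples(rec) / rec$sampling$rate_hz

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s, condition %s: %.1f s @ %g Hz (%d samples)\n",
              x$subject_id, x$condition_id, duration_s(x),
              x$sampling$rate_hz, n_samples(x)))
  cat(sprintf("  still interval: [%.2f, %.2f] s\n",
              x$still_interval[1L], x$still_interval[2L]))
  invisible(x)
}

#' FOG event annotation track
#'
#' An ordered, non-overlapping set of freezing-of-gait episodes, each given by
#' its clinician-annotated onset (the arrest of the alternating stepping
#' pattern) and termination time in seconds.
#'
#' @param start_s,end_s Numeric vectors of equal length; each event must have
#'   `start_s < end_s` and consecutive events must not overlap.
#' @param duration_s Optional recording duration for bounds checking.
#' @return A `fog_events` data.frame with columns `start_s`, `end_s`, sorted
#'   by onset.
#' @examples
#' fog_events(c(10, 5), c(11.5, 7))  # returned sorted by onset
#' @export
fog_events <- function(start_s = numeric(), end_s = numeric(),
                       duration_s = NULL) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s))
    stop("start_s and end_s must have equal length")
  if (length(start_s)) {
    stopifnot(all(is.finite(start_s)), all(is.finite(end_s)))
    if (any(start_s < 0)) stop("FOG events must start at time >= 0")
    bad <- which(start_s >= end_s)
    if (length(bad))
      stop(sprintf("FOG event %d has start_s (%g) >= end_s (%g)",
                   bad[1L], start_s[bad[1L]], end_s[bad[1L]]))
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    ov <- which(utils::head(end_s, -1L) > utils::tail(start_s, -1L))
    if (length(ov))
      stop(sprintf(
        "overlapping FOG events: (%g, %g) and (%g, %g)",
        start_s[ov[1L]], end_s[ov[1L]],
        start_s[ov[1L] + 1L], end_s[ov[1L] + 1L]))
    if (!is.null(duration_s) && any(end_s > duration_s + 1e-9))
      stop("FOG event extends beyond the recording duration")
  }
  structure(data.frame(start_s = start_s, end_s = end_s),
            class = c("fog_events", "data.frame"))
}

#' Names of the eight gait features
#'
#' The eight per-window features, in canonical order: turning degrees,
#' left-right cross-correlation, left-right average SD, left-right SD
#' difference, lower-back SD, locomotor-band power, freezing-band power, and
#' freezing index.
#'
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  c("turning_degrees", "lr_xcorr", "lr_avg_sd", "lr_diff_sd",
    "lowerback_sd", "locomotor_power", "freezing_power", "freezing_index")
}

#' Labels a 2-s window can carry after segmentation
#' @return Character vector of the four window labels.
#' @export
window_labels <- function() {
  c("gait", "pre_fog", "discarded_motion", "discarded_overlap")
}

# internal: slice the per-channel samples of one window (0-based start,
# half-open) out of a recording
.window_slice <- function(rec, start_sample, n) {
  idx <- (start_sample + 1L):(start_sample + n)
  if (start_sample < 0L || (start_sample + n) > n_samples(rec))
    stop(sprintf("window [%d, %d) out of recording bounds [0, %d)",
                 start_sample, start_sample + n, n_samples(rec)))
  lapply(rec$streams, function(s)
    list(acc = s$acc[idx, , drop = FALSE], gyro = s$gyro[idx, , drop = FALSE]))
}
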