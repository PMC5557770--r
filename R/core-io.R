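# Readers/writers for the package's plain-text artifact formats.
#
# Recording CSV: t_s + 6 channels per location (la/ra/lb x acc/gyro x
# ap/ml/v), with a JSON sidecar holding subject_id, condition_id, rate_hz and
# the still interval. Numbers are written with 17 significant digits so a
# write -> read round trip is bit-identical.

.channel_columns <- function() {
  unlist(lapply(.loc_codes, function(code)
    paste(code, rep(c("acc", "gyro"), each = 3L), .axis_names, sep = "_")),
    use.names = FALSE)
}

.meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a recording to CSV (+ JSON sidecar)
#'
#' @param rec A [recording()].
#' @param path CSV output path. Metadata (subject, condition, rate, still
#'   interval) goes to `meta_path`.
#' @param meta_path JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, meta_path = .meta_path(path)) {
  stopifnot(inherits(rec, "recording"))
  n <- n_samples(rec)
  cols <- list(t_s = (seq_len(n) - 1L) / rec$sampling$rate_hz)
  for (loc in sensor_locations()) {
    code <- .loc_codes[[loc]]
    s <- rec$streams[[loc]]
    for (ax in 1:3) cols[[paste(code, "acc", .axis_names[ax], sep = "_")]] <-
        s$acc[, ax]
    for (ax in 1:3) cols[[paste(code, "gyro", .axis_names[ax], sep = "_")]] <-
        s$gyro[, ax]
  }
  dt <- data.table::as.data.table(
    lapply(cols, function(x) formatC(x, digits = 17, format = "g")))
  data.table::fwrite(dt, path, quote = FALSE)
  meta <- list(subject_id = rec$subject_id, condition_id = rec$condition_id,
               rate_hz = rec$sampling$rate_hz,
               window_s = rec$sampling$window_s,
               still_interval = rec$still_interval,
               acc_units = "m/s^2", gyro_units = "rad/s")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from CSV (+ JSON sidecar)
#'
#' Validates that all 18 channel columns are present and finite; errors name
#' the offending column (and row, for non-finite values).
#'
#' @param path CSV path written by [write_recording()] or following the same
#'   schema.
#' @param meta_path JSON sidecar path.
#' @return A [recording()].
#' @export
read_recording <- function(path, meta_path = .meta_path(path)) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dt <- data.table::fread(path, colClasses = "numeric")
  need <- .channel_columns()
  missing <- setdiff(need, names(dt))
  if (length(missing))
    stop("recording CSV is missing column(s): ", paste(missing, collapse = ", "))
  streams <- lapply(sensor_locations(), function(loc) {
    code <- .loc_codes[[loc]]
    grab <- function(kind) {
      m <- as.matrix(dt[, paste(code, kind, .axis_names, sep = "_"),
                        with = FALSE])
      colnames(m) <- .axis_names
      m
    }
    sensor_stream(loc, grab("acc"), grab("gyro"))
  })
  recording(meta$subject_id, meta$condition_id, streams,
            sampling_config(meta$rate_hz,
                            if (!is.null(meta$window_s)) meta$window_s else 2),
            meta$still_interval)
}

#' Read a FOG annotation track from CSV
#'
#' Expects columns `start_s,end_s`; an empty or header-only file yields an
#' empty track. Overlapping events are a validation error naming the pair.
#'
#' @param path CSV path.
#' @param duration_s Optional recording duration for bounds checking.
#' @return A [fog_events()] track.
#' @export
read_annotations <- function(path, duration_s = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (file.size(path) == 0L) return(fog_events())
  dt <- data.table::fread(path)
  if (nrow(dt) == 0L) return(fog_events())
  if (!all(c("start_s", "end_s") %in% names(dt)))
    stop("annotation CSV must have columns start_s,end_s")
  fog_events(dt$start_s, dt$end_s, duration_s = duration_s)
}

#' Write a FOG annotation track to CSV
#' @param events A [fog_events()] track.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  stopifnot(inherits(events, "fog_events"))
  dt <- data.table::data.table(
    start_s = formatC(events$start_s, digits = 17, format = "g"),
    end_s = formatC(events$end_s, digits = 17, format = "g"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Write / read a window table
#'
#' Columns: `subject, condition, start_sample, n_samples, label`.
#'
#' @param windows Window data.frame from [segment_recording()].
#' @param path CSV path.
#' @return `path` (write) or the window data.frame (read).
#' @export
write_windows <- function(windows, path) {
  data.table::fwrite(data.table::as.data.table(windows), path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  as.data.frame(data.table::fread(path,
    colClasses = list(character = c("subject", "condition", "label"))))
}

#' Write / read a feature table
#'
#' Window key columns plus the eight named feature columns of
#' [feature_names()], written with full precision.
#'
#' @param features Feature data.frame from [extract_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_features <- function(features, path) {
  dt <- data.table::as.data.table(features)
  for (f in intersect(feature_names(), names(dt)))
    data.table::set(dt, j = f, value = formatC(dt[[f]], digits = 17,
                                               format = "g"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  for (f in intersect(feature_names(), names(df)))
    df[[f]] <- as.numeric(df[[f]])
  df
}

#' Aggregate per-subject classifier performance into a mean row
#'
#' Averages AUC, sensitivity, specificity and threshold over subjects,
#' skipping rows where the metrics are undefined (single-class test
#' subjects). Values are reported rounded to two decimals alongside the
#' exact means.
#'
#' @param rows Data.frame with columns `subject_id, auc, sensitivity,
#'   specificity, threshold`.
#' @param digits Rounding applied to the `auc`..`threshold` columns of the
#'   returned row (default 2, the conventional reporting precision).
#' @return One-row data.frame with `subject_id = "mean"`.
#' @export
summarize_eval <- function(rows, digits = 2) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  metrics <- c("auc", "sensitivity", "specificity", "threshold")
  stopifnot(all(c("subject_id", metrics) %in% names(rows)))
  ok <- stats::complete.cases(rows[, metrics])
  if (!any(ok)) stop("no rows with defined metrics to average")
  out <- data.frame(subject_id = "mean")
  for (m in metrics) out[[m]] <- round(mean(rows[[m]][ok]), digits)
  out
}

#' Write classifier evaluation rows (plus a mean row) to CSV
#'
#' @param rows Per-subject evaluation rows (see [loso_evaluate()]).
#' @param path Output CSV path.
#' @param add_mean Append the [summarize_eval()] mean row? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path, add_mean = TRUE) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("cannot write an empty result table")
  out <- rows
  if (add_mean) {
    m <- summarize_eval(rows)
    for (col in setdiff(names(rows), names(m))) m[[col]] <- NA
    out <- rbind(rows, m[, names(rows)])
  }
  data.table::fwrite(data.table::as.data.table(out), path)
  invisible(path)
}
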