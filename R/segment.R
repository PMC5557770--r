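# Window segmentation: pre-FOG candidate extraction, gait-window tiling of
# the remaining data, and the sufficient-motion check.

#' Motion-check parameters
#'
#' A sample is "motionless" when both ankle gyroscope norms are below
#' `gyro_thresh` and the lower-back acceleration norm lies within
#' `acc_tol_frac` of the still-calibration reference. A window has
#' insufficient motion when strictly more than `motionless_frac` of its
#' samples are motionless (exactly half counts as sufficient motion).
#'
#' @param gyro_thresh Ankle angular-velocity norm threshold (rad/s).
#' @param acc_tol_frac Fractional tolerance around the acceleration
#'   reference.
#' @param motionless_frac Fraction of motionless samples above which a
#'   window is discarded.
#' @return A `motion_params` list.
#' @export
motion_params <- function(gyro_thresh = 0.5, acc_tol_frac = 0.10,
                          motionless_frac = 0.50) {
  stopifnot(gyro_thresh > 0, acc_tol_frac > 0, acc_tol_frac < 1,
            motionless_frac > 0, motionless_frac < 1)
  structure(list(gyro_thresh = gyro_thresh, acc_tol_frac = acc_tol_frac,
                 motionless_frac = motionless_frac),
            class = "motion_params")
}

.row_norms <- function(m) sqrt(rowSums(m * m))

#' Acceleration-norm reference from the still calibration interval
#'
#' Mean of the lower-back acceleration norm over the recording's still
#' interval. Near gravity (9.81 m/s^2) for a correctly calibrated sensor; a
#' warning is raised if the estimate falls outside 8-12 m/s^2.
#'
#' @param rec A [recording()].
#' @return Reference acceleration norm in m/s^2.
#' @export
compute_still_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rate <- rec$sampling$rate_hz
  i0 <- time_to_index(rec$still_interval[1L], rate)
  i1 <- time_to_index(rec$still_interval[2L], rate)
  i1 <- min(i1, n_samples(rec))
  if (i0 < 0L || i1 <= i0)
    stop("still interval lies outside the recording")
  ref <- mean(.row_norms(rec$streams$lower_back$acc[(i0 + 1L):i1, ,
                                                    drop = FALSE]))
  if (ref < 8 || ref > 12)
    warning(sprintf(
      "still acceleration reference %.2f m/s^2 is far from gravity; check calibration",
      ref))
  ref
}

#' Per-sample motionless test
#'
#' A sample is motionless iff both ankle gyroscope norms are below the
#' threshold AND the lower-back acceleration norm falls in
#' `acc_ref * (1 - tol, 1 + tol)`. `is_motionless` tests one sample from its
#' three per-location measurement vectors; `motionless_mask` evaluates every
#' sample of a recording at once.
#'
#' @param gyro_left,gyro_right Length-3 angular-velocity vectors (rad/s).
#' @param acc_lowerback Length-3 acceleration vector (m/s^2).
#' @param acc_ref Reference acceleration norm from
#'   [compute_still_reference()].
#' @param params A [motion_params()].
#' @return Logical (scalar for `is_motionless`, per-sample vector for
#'   `motionless_mask`).
#' @export
is_motionless <- function(gyro_left, gyro_right, acc_lowerback, acc_ref,
                          params = motion_params()) {
  stopifnot(length(gyro_left) == 3L, length(gyro_right) == 3L,
            length(acc_lowerback) == 3L, acc_ref > 0)
  nl <- sqrt(sum(gyro_left^2))
  nr <- sqrt(sum(gyro_right^2))
  na_ <- sqrt(sum(acc_lowerback^2))
  nl < params$gyro_thresh && nr < params$gyro_thresh &&
    na_ > acc_ref * (1 - params$acc_tol_frac) &&
    na_ < acc_ref * (1 + params$acc_tol_frac)
}

#' @rdname is_motionless
#' @param rec A [recording()].
#' @export
motionless_mask <- function(rec, acc_ref = compute_still_reference(rec),
                            params = motion_params()) {
  stopifnot(inherits(rec, "recording"))
  nl <- .row_norms(rec$streams$left_ankle$gyro)
  nr <- .row_norms(rec$streams$right_ankle$gyro)
  na_ <- .row_norms(rec$streams$lower_back$acc)
  nl < params$gyro_thresh & nr < params$gyro_thresh &
    na_ > acc_ref * (1 - params$acc_tol_frac) &
    na_ < acc_ref * (1 + params$acc_tol_frac)
}

#' Sufficient-motion check for one window
#'
#' @param start_sample 0-based first sample of the window.
#' @param mask Per-sample motionless logical vector from
#'   [motionless_mask()].
#' @param sampling A [sampling_config()].
#' @param params A [motion_params()].
#' @return TRUE if the window has sufficient motion (motionless fraction not
#'   strictly above `motionless_frac`).
#' @export
has_sufficient_motion <- function(start_sample, mask,
                                  sampling = sampling_config(),
                                  params = motion_params()) {
  w <- sampling$window_samples
  if (start_sample < 0L || start_sample + w > length(mask))
    stop(sprintf("window [%d, %d) out of bounds [0, %d)",
                 start_sample, start_sample + w, length(mask)))
  frac <- sum(mask[(start_sample + 1L):(start_sample + w)]) / w
  !(frac > params$motionless_frac)
}

# FOG intervals in 0-based half-open sample coordinates
.fog_sample_intervals <- function(annotations, rate) {
  if (nrow(annotations) == 0L)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = time_to_index(annotations$start_s, rate),
             end = time_to_index(annotations$end_s, rate))
}

.intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Extract pre-FOG candidate windows
#'
#' One candidate per FOG event, covering the 2 s ending at onset. Candidates
#' whose support overlaps an earlier FOG interval are labeled
#' `discarded_overlap` (gait before FOG cannot be studied there); candidates
#' failing the sufficient-motion check are labeled `discarded_motion`;
#' candidates extending before the start of the recording are dropped.
#'
#' @param rec A [recording()].
#' @param annotations A [fog_events()] track.
#' @param sampling A [sampling_config()].
#' @param params A [motion_params()].
#' @param acc_ref Acceleration reference; computed from the still interval
#'   by default.
#' @return Window data.frame (`subject, condition, start_sample, n_samples,
#'   label`).
#' @export
extract_prefog_windows <- function(rec, annotations,
                                   sampling = rec$sampling,
                                   params = motion_params(),
                                   acc_ref = compute_still_reference(rec)) {
  stopifnot(inherits(rec, "recording"), inherits(annotations, "fog_events"))
  w <- sampling$window_samples
  rate <- sampling$rate_hz
  fog <- .fog_sample_intervals(annotations, rate)
  mask <- motionless_mask(rec, acc_ref, params)
  rows <- list()
  for (i in seq_len(nrow(fog))) {
    onset <- fog$start[i]
    cs <- onset - w
    if (cs < 0L) next  # degenerate: support precedes the recording
    other <- fog[-i, , drop = FALSE]
    lab <- if (any(.intervals_overlap(cs, onset, other$start, other$end)))
      "discarded_overlap"
    else if (!has_sufficient_motion(cs, mask, sampling, params))
      "discarded_motion"
    else "pre_fog"
    rows[[length(rows) + 1L]] <-
      data.frame(subject = rec$subject_id, condition = rec$condition_id,
                 start_sample = cs, n_samples = w, label = lab,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(subject = character(), condition = character(),
                      start_sample = integer(), n_samples = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Extract gait windows from the non-FOG, non-pre-FOG remainder
#'
#' FOG intervals and all pre-FOG candidate supports (whether kept or
#' discarded) are removed; each remaining continuous portion of at least one
#' window length is tiled with non-overlapping windows, trimming an equal
#' slack from both ends (odd slack: the extra sample is dropped at the
#' end). Windows failing the sufficient-motion check are labeled
#' `discarded_motion`, the rest `gait`.
#'
#' @inheritParams extract_prefog_windows
#' @param prefog_windows Pre-FOG candidates from
#'   [extract_prefog_windows()]; accepted for interface symmetry, but the
#'   excluded supports are recomputed from `annotations` so that candidates
#'   clipped at the recording start are excluded too.
#' @return Window data.frame as in [extract_prefog_windows()].
#' @export
extract_gait_windows <- function(rec, annotations, prefog_windows = NULL,
                                 sampling = rec$sampling,
                                 params = motion_params(),
                                 acc_ref = compute_still_reference(rec)) {
  stopifnot(inherits(rec, "recording"), inherits(annotations, "fog_events"))
  w <- sampling$window_samples
  rate <- sampling$rate_hz
  n <- n_samples(rec)
  fog <- .fog_sample_intervals(annotations, rate)
  excluded <- rep(FALSE, n)
  for (i in seq_len(nrow(fog))) {
    s <- max(0L, fog$start[i] - w)          # candidate support + FOG itself
    e <- min(n, fog$end[i])
    if (e > s) excluded[(s + 1L):e] <- TRUE
  }
  mask <- motionless_mask(rec, acc_ref, params)
  rows <- list()
  r <- rle(excluded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths               # 0-based run starts
  for (j in seq_along(r$values)) {
    if (r$values[j]) next
    L <- r$lengths[j]
    k <- L %/% w
    if (k < 1L) next
    lead <- (L - k * w) %/% 2L
    ws <- starts[j] + lead + (seq_len(k) - 1L) * w
    lab <- ifelse(vapply(ws, has_sufficient_motion, logical(1), mask,
                         sampling, params),
                  "gait", "discarded_motion")
    rows[[length(rows) + 1L]] <-
      data.frame(subject = rec$subject_id, condition = rec$condition_id,
                 start_sample = as.integer(ws), n_samples = w, label = lab,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(subject = character(), condition = character(),
                      start_sample = integer(), n_samples = integer(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Segment a recording into pre-FOG, gait and discarded windows
#'
#' Convenience wrapper running [extract_prefog_windows()] then
#' [extract_gait_windows()] and returning the combined table ordered by
#' start sample, with the acceleration reference attached as attribute
#' `acc_ref`.
#'
#' @inheritParams extract_prefog_windows
#' @return Window data.frame sorted by `start_sample`.
#' @export
segment_recording <- function(rec, annotations, sampling = rec$sampling,
                              params = motion_params(),
                              acc_ref = compute_still_reference(rec)) {
  pf <- extract_prefog_windows(rec, annotations, sampling, params, acc_ref)
  gw <- extract_gait_windows(rec, annotations, pf, sampling, params, acc_ref)
  out <- rbind(pf, gw)
  out <- out[order(out$start_sample), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "acc_ref") <- acc_ref
  out
}
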