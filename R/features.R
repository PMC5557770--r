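# The eight per-window gait features.
#
# Spectral estimator: rectangular-window periodogram of the mean-removed
# window, one-sided, scaled so that the sum over all bins equals the biased
# variance of the window (Parseval). At 128 Hz and 256 samples the bin
# width is 0.5 Hz. Band edges are half-open [f1, f2), so the shared 3 Hz
# edge belongs to the freezing band only.

#' Frequency-band definition
#'
#' The locomotor band (0.5-3 Hz) holds the stride (~1 Hz) and step (~2 Hz)
#' periodicities of walking; the freezing band (3-8 Hz) holds the leg
#' trembling characteristic of freezing episodes.
#'
#' @param locomotor,freezing Numeric `(f1, f2)` band edges in Hz.
#' @return A `band_definition` list.
#' @export
band_definition <- function(locomotor = c(0.5, 3), freezing = c(3, 8)) {
  stopifnot(length(locomotor) == 2L, length(freezing) == 2L,
            locomotor[1L] < locomotor[2L], freezing[1L] < freezing[2L],
            locomotor[2L] <= freezing[1L])
  structure(list(locomotor = locomotor, freezing = freezing),
            class = "band_definition")
}

#' Cross-correlation search parameters
#'
#' Lag range for the left-right ankle cross-correlation: 0.25-1.25 s covers
#' one alternating step-to-stride period, where a healthy gait pattern peaks.
#'
#' @param lag_min_s,lag_max_s Lag range in seconds.
#' @return An `xcorr_params` list.
#' @export
xcorr_params <- function(lag_min_s = 0.25, lag_max_s = 1.25) {
  stopifnot(lag_min_s > 0, lag_min_s < lag_max_s)
  structure(list(lag_min_s = lag_min_s, lag_max_s = lag_max_s),
            class = "xcorr_params")
}

#' Turning degrees from the lower-back vertical angular velocity
#'
#' The vertical angular velocity is low-pass filtered at `cutoff_hz` with a
#' zero-phase (forward-backward) Butterworth filter, integrated with the
#' trapezoidal rule, and the absolute net angle is returned in degrees.
#' Zero-phase filtering avoids integration bias from filter delay; the
#' magnitude is returned because turn direction is arbitrary.
#'
#' @param gyro_v Vertical angular velocity samples (rad/s).
#' @param rate_hz Sampling rate.
#' @param cutoff_hz Low-pass cutoff; default 1.5 Hz keeps turning dynamics
#'   and rejects step-frequency wobble.
#' @param order Butterworth order (default 4).
#' @return Absolute net turn angle in degrees.
#' @export
turning_degrees <- function(gyro_v, rate_hz, cutoff_hz = 1.5, order = 4) {
  n <- length(gyro_v)
  if (n < 3L * (order + 1L))
    stop("input too short for the low-pass filter warm-up")
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2))
  # odd-reflection padding suppresses the forward-backward filter's edge
  # transients (which otherwise bias the integral of slow signals); the pad
  # spans roughly three time constants of the low cutoff
  np <- min(n - 1L, 3L * ceiling(rate_hz / cutoff_hz))
  pad <- c(2 * gyro_v[1L] - gyro_v[(np + 1L):2L],
           gyro_v,
           2 * gyro_v[n] - gyro_v[(n - 1L):(n - np)])
  f <- signal::filtfilt(bf, pad)[np + seq_len(n)]
  ang <- sum((f[-1L] + f[-n]) / 2) / rate_hz
  abs(ang) * 180 / pi
}

.detrend_linear <- function(x) {
  n <- length(x)
  stats::lsfit(seq_len(n), x)$residuals
}

#' Left-right ankle cross-correlation
#'
#' Maximum of the unbiased cross-correlation
#' `r(k) = sum(x(t) y(t+k)) / (N - |k|)` between the linearly detrended
#' left- and right-ankle mediolateral angular velocities, over lags
#' `|k|` in `[lag_min_s, lag_max_s]` searched in both directions (leg
#' leadership is arbitrary). The value quantifies joint movement amplitude
#' and phase alternation; it is a covariance, in (rad/s)^2, not normalized
#' to `[-1, 1]`.
#'
#' @param left,right Equal-length mediolateral angular-velocity windows
#'   (rad/s).
#' @param rate_hz Sampling rate.
#' @param params An [xcorr_params()].
#' @return Maximum unbiased cross-correlation ((rad/s)^2).
#' @export
lr_cross_correlation <- function(left, right, rate_hz,
                                 params = xcorr_params()) {
  n <- length(left)
  if (length(right) != n)
    stop("left and right windows differ in length (", n, " vs ",
         length(right), ")")
  x <- .detrend_linear(left)
  y <- .detrend_linear(right)
  k0 <- as.integer(round(params$lag_min_s * rate_hz))
  k1 <- as.integer(round(params$lag_max_s * rate_hz))
  if (k1 >= n) stop("maximum lag exceeds the window length")
  best <- -Inf
  for (k in k0:k1) {
    m <- n - k
    best <- max(best,
                sum(x[seq_len(m)] * y[seq_len(m) + k]) / m,   # y lags x
                sum(y[seq_len(m)] * x[seq_len(m) + k]) / m)   # x lags y
  }
  best
}

#' Sample standard deviation of a signal window
#'
#' The n-1 denominator form; errors on fewer than two samples.
#'
#' @param x Numeric samples.
#' @return SD in the units of `x`.
#' @export
signal_sd <- function(x) {
  if (length(x) < 2L) stop("signal_sd needs at least 2 samples")
  stats::sd(x)
}

#' Left-right SD summary statistics
#'
#' Average and absolute difference of the per-ankle mediolateral
#' angular-velocity SDs: overall range of leg movement, and left-right
#' amplitude asymmetry, respectively.
#'
#' @param left,right Mediolateral angular-velocity windows (rad/s).
#' @return SD statistic in rad/s.
#' @export
lr_avg_sd <- function(left, right) (signal_sd(left) + signal_sd(right)) / 2

#' @rdname lr_avg_sd
#' @export
lr_diff_sd <- function(left, right) abs(signal_sd(left) - signal_sd(right))

#' Band power of a window
#'
#' One-sided periodogram power of the mean-removed window summed over
#' frequency bins with `f1 <= f < f2`. The estimator satisfies Parseval's
#' identity: summing over a partition of `[0, rate/2]` recovers the biased
#' variance of the window.
#'
#' @param x Signal window (e.g. anteroposterior acceleration, m/s^2).
#' @param band Numeric `(f1, f2)` in Hz, inside `(0, rate_hz / 2]`.
#' @param rate_hz Sampling rate.
#' @return Band power in squared input units.
#' @export
band_power <- function(x, band, rate_hz) {
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  if (band[1L] <= 0 || band[2L] > rate_hz / 2 + 1e-12)
    stop(sprintf("band [%g, %g] outside (0, %g]", band[1L], band[2L],
                 rate_hz / 2))
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2
  half <- n %/% 2L
  ps <- p[seq_len(half + 1L)]             # k = 0 .. n/2
  if (half >= 1L) {
    dbl <- 2L:(half + ((n %% 2L) == 1L))  # double all but DC (and Nyquist)
    ps[dbl] <- 2 * ps[dbl]
  }
  freq <- (0:half) * rate_hz / n
  sel <- freq >= band[1L] & freq < band[2L]
  # a band ending exactly at Nyquist is closed there, so a partition of
  # (0, rate/2] conserves total power (Parseval)
  if (abs(band[2L] - rate_hz / 2) < 1e-12) sel <- sel | freq == band[2L]
  sum(ps[sel])
}

#' Freezing index of a window
#'
#' Ratio of freezing-band to locomotor-band power of the anteroposterior
#' ankle acceleration, computed per ankle and averaged (mean of ratios). A
#' small-denominator guard makes the ratio total: the locomotor power is
#' floored at `eps` and the ratio capped at `cap`. Windows with no
#' locomotor content are normally discarded upstream by the motion check,
#' so the guard only matters for degenerate inputs.
#'
#' @param ap_left,ap_right Anteroposterior acceleration windows for the two
#'   ankles (m/s^2).
#' @param rate_hz Sampling rate.
#' @param bands A [band_definition()].
#' @param eps Locomotor-power floor ((m/s^2)^2).
#' @param cap Upper bound on each per-ankle ratio.
#' @return Dimensionless freezing index.
#' @export
freezing_index <- function(ap_left, ap_right, rate_hz,
                           bands = band_definition(),
                           eps = 1e-8, cap = 1e4) {
  fi_one <- function(x) {
    lp <- band_power(x, bands$locomotor, rate_hz)
    fp <- band_power(x, bands$freezing, rate_hz)
    min(fp / max(lp, eps), cap)
  }
  (fi_one(ap_left) + fi_one(ap_right)) / 2
}

#' Extract the eight features for segmented windows
#'
#' Computes, for every `gait` and `pre_fog` window, the eight features:
#' turning degrees (lower-back vertical gyro), left-right
#' cross-correlation, average SD and SD difference (ankle mediolateral
#' gyros), lower-back SD (AP acceleration), locomotor- and freezing-band
#' power and freezing index (ankle AP accelerations, left/right averaged).
#' Every feature is a pure function of the window's samples.
#'
#' @param windows Window data.frame from [segment_recording()].
#' @param rec The [recording()] the windows index into.
#' @param bands A [band_definition()].
#' @param xcorr An [xcorr_params()].
#' @param fi_eps,fi_cap Freezing-index guard, see [freezing_index()].
#' @return Data.frame: window key columns plus the eight
#'   [feature_names()] columns, one row per gait/pre-FOG window.
#' @export
extract_features <- function(windows, rec, bands = band_definition(),
                             xcorr = xcorr_params(),
                             fi_eps = 1e-8, fi_cap = 1e4) {
  stopifnot(inherits(rec, "recording"))
  keep <- windows$label %in% c("gait", "pre_fog")
  windows <- windows[keep, , drop = FALSE]
  if (nrow(windows) == 0L) {
    empty <- windows[, c("subject", "condition", "start_sample", "n_samples",
                         "label")]
    for (f in feature_names()) empty[[f]] <- numeric(0)
    return(empty)
  }
  rate <- rec$sampling$rate_hz
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sl <- .window_slice(rec, windows$start_sample[i], windows$n_samples[i])
    l_ml <- sl$left_ankle$gyro[, "ml"]
    r_ml <- sl$right_ankle$gyro[, "ml"]
    l_ap <- sl$left_ankle$acc[, "ap"]
    r_ap <- sl$right_ankle$acc[, "ap"]
    out[[i]] <- data.frame(
      turning_degrees = turning_degrees(sl$lower_back$gyro[, "v"], rate),
      lr_xcorr = lr_cross_correlation(l_ml, r_ml, rate, xcorr),
      lr_avg_sd = lr_avg_sd(l_ml, r_ml),
      lr_diff_sd = lr_diff_sd(l_ml, r_ml),
      lowerback_sd = signal_sd(sl$lower_back$acc[, "ap"]),
      locomotor_power = (band_power(l_ap, bands$locomotor, rate) +
                           band_power(r_ap, bands$locomotor, rate)) / 2,
      freezing_power = (band_power(l_ap, bands$freezing, rate) +
                          band_power(r_ap, bands$freezing, rate)) / 2,
      freezing_index = freezing_index(l_ap, r_ap, rate, bands,
                                      fi_eps, fi_cap))
  }
  cbind(windows[, c("subject", "condition", "start_sample", "n_samples",
                    "label")],
        do.call(rbind, out), row.names = NULL)
}
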