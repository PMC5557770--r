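# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive, brute-force versions of the textbook
# definitions and share no code with the package internals.

# unbiased cross-correlation by explicit double loop, with detrending done
# via closed-form simple-regression coefficients
oracle_detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  b <- sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
  a <- mean(x) - b * mean(t)
  x - (a + b * t)
}

oracle_xcorr_curve <- function(x, y, k0, k1) {
  x <- oracle_detrend(x); y <- oracle_detrend(y)
  n <- length(x)
  ks <- k0:k1
  pos <- vapply(ks, function(k) {
    s <- 0
    for (t in 1:(n - k)) s <- s + x[t] * y[t + k]
    s / (n - k)
  }, numeric(1))
  neg <- vapply(ks, function(k) {
    s <- 0
    for (t in 1:(n - k)) s <- s + y[t] * x[t + k]
    s / (n - k)
  }, numeric(1))
  list(lags = c(-rev(ks), ks), values = c(rev(neg), pos))
}

oracle_xcorr_max <- function(x, y, rate, lag_min = 0.25, lag_max = 1.25) {
  k0 <- round(lag_min * rate); k1 <- round(lag_max * rate)
  max(oracle_xcorr_curve(x, y, k0, k1)$values)
}

# paired t-test from the textbook formula
oracle_paired_t <- function(gait, prefog) {
  d <- prefog - gait
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Benjamini-Yekutieli step-up adjustment from the definition
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  raw <- pmin(1, ps * m * cm / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by exhaustive pair counting, ties worth 1/2
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Youden point by exhaustive threshold enumeration (midpoints), tie-broken
# toward higher specificity then higher threshold
oracle_youden <- function(scores, pos) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else s
  grid <- data.frame(
    th = cand,
    sens = vapply(cand, function(th) mean(scores[pos] > th), numeric(1)),
    spec = vapply(cand, function(th) mean(scores[!pos] <= th), numeric(1)))
  grid$j <- round(grid$sens + grid$spec - 1, 12)  # exact-fraction ties
  grid <- grid[order(-grid$j, -grid$spec, -grid$th), ]
  grid[1, ]
}

# brute-force sample-level window labeler: marks every sample of the
# recording as fog / pre-FOG-candidate / other, then scans runs of "other"
# sample by sample. Independent re-derivation of the segmentation rules.
oracle_segment <- function(rec, ann, sampling = rec$sampling,
                           params = motion_params()) {
  rate <- sampling$rate_hz
  w <- sampling$window_samples
  n <- prefog::n_samples(rec)
  acc_ref <- compute_still_reference(rec)
  gl <- sqrt(rowSums(rec$streams$left_ankle$gyro^2))
  gr <- sqrt(rowSums(rec$streams$right_ankle$gyro^2))
  ab <- sqrt(rowSums(rec$streams$lower_back$acc^2))
  still <- gl < params$gyro_thresh & gr < params$gyro_thresh &
    ab > acc_ref * (1 - params$acc_tol_frac) &
    ab < acc_ref * (1 + params$acc_tol_frac)
  insufficient <- function(s0) {           # 0-based window start
    mean(still[(s0 + 1):(s0 + w)]) > params$motionless_frac
  }
  lab <- rep("other", n)                   # per-sample marks
  fs <- floor(ann$start_s * rate + 1e-9)
  fe <- floor(ann$end_s * rate + 1e-9)
  for (i in seq_along(fs)) lab[(fs[i] + 1):fe[i]] <- "fog"
  rows <- list()
  add <- function(s0, label)
    rows[[length(rows) + 1]] <<- data.frame(
      subject = rec$subject_id, condition = rec$condition_id,
      start_sample = as.integer(s0), n_samples = w, label = label,
      stringsAsFactors = FALSE)
  # pre-FOG candidates, in onset order
  for (i in seq_along(fs)) {
    cs <- fs[i] - w
    if (cs >= 0) {
      span <- (cs + 1):fs[i]
      if (any(lab[span] == "fog"))
        add(cs, "discarded_overlap")
      else if (insufficient(cs))
        add(cs, "discarded_motion")
      else
        add(cs, "pre_fog")
    }
    if (fs[i] >= 1) {
      span <- max(1, cs + 1):fs[i]
      lab[span] <- ifelse(lab[span] == "fog", "fog", "cand")
    }
  }
  # gait windows: scan runs of "other" one sample at a time
  i <- 1
  while (i <= n) {
    if (lab[i] != "other") { i <- i + 1; next }
    j <- i
    while (j < n && lab[j + 1] == "other") j <- j + 1
    L <- j - i + 1
    k <- L %/% w
    if (k >= 1) {
      lead <- (L - k * w) %/% 2
      for (q in seq_len(k)) {
        s0 <- (i - 1) + lead + (q - 1) * w
        add(s0, if (insufficient(s0)) "discarded_motion" else "gait")
      }
    }
    i <- j + 1
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start_sample), ]
  rownames(out) <- NULL
  out
}
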