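# Fixture builders. Everything is generated in code at test time.

# hand-built recording from explicit per-sample norms: ankle gyro norms are
# placed on the ml axis, the lower-back acceleration norm on the v axis, so
# the motion check sees exactly the requested values
make_norm_recording <- function(gyro_l_norm, gyro_r_norm, acc_lb_norm,
                                rate_hz = 128, still = c(0, 1),
                                subject = "T1", condition = "c") {
  n <- length(gyro_l_norm)
  zero <- matrix(0, n, 3)
  acc_g <- zero; acc_g[, 3] <- 9.81
  la <- sensor_stream("left_ankle", acc_g, cbind(0, gyro_l_norm, 0))
  ra <- sensor_stream("right_ankle", acc_g, cbind(0, gyro_r_norm, 0))
  lb <- sensor_stream("lower_back", cbind(0, 0, acc_lb_norm), zero)
  recording(subject, condition, list(la, ra, lb),
            sampling_config(rate_hz, 2), still)
}

# moving/still per-sample pattern: "moving" samples get ankle gyro norm 1.0
# (fails the motionless test), "still" samples norm 0 with acc at gravity
make_pattern_recording <- function(moving, rate_hz = 128,
                                   still = c(0, 1), subject = "T1",
                                   condition = "c") {
  gy <- ifelse(moving, 1.0, 0.0)
  make_norm_recording(gy, gy, rep(9.81, length(moving)), rate_hz, still,
                      subject, condition)
}

# random FOG-provoking timeline of <= 60 s exercising all the edge cases:
# short portions, rests, back-to-back FOG (overlapping candidates), abrupt
# onsets after stillness
random_timeline <- function(seed) {
  set.seed(seed)
  segs <- list(seg_still(runif(1, 2, 3.5)))
  total <- segs[[1]]$duration_s
  repeat {
    type <- sample(c("walk", "still", "turn", "fog"), 1,
                   prob = c(0.4, 0.15, 0.15, 0.3))
    dur <- switch(type,
                  walk = runif(1, 1, 6),     # short walks -> <2 s portions
                  still = runif(1, 1, 4),
                  turn = runif(1, 2.5, 4),
                  fog = runif(1, 1.5, 4))
    if (total + dur > 55) break
    prev <- segs[[length(segs)]]
    seg <- switch(type,
                  walk = seg_walk(dur),
                  still = seg_still(dur),
                  turn = seg_turn(runif(1, 90, 360), dur),
                  fog = seg_fog(dur, abrupt = !(prev$type %in%
                                                  c("walk", "turn") &&
                                                prev$duration_s >= 2)))
    segs <- c(segs, list(seg))
    total <- total + dur
  }
  if (length(segs) < 3) segs <- c(segs, list(seg_walk(5), seg_fog(3)))
  segs
}

# full cohort -> paired statistics, the common tail of several tests
cohort_stats <- function(scenario, alpha = 0.05) {
  fr <- analyze_recordings(generate_cohort(scenario))
  pairs <- build_paired_samples(fr$features)
  list(windows = fr$windows, features = fr$features, pairs = pairs,
       stats = run_group_analysis(pairs, alpha))
}
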