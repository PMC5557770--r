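test_that("generation is deterministic for a fixed seed", {
  segs <- list(seg_still(2.5), seg_walk(6), seg_fog(3), seg_walk(3))
  a <- generate_recording(segs, seed = 11)
  b <- generate_recording(segs, seed = 11)
  for (loc in sensor_locations()) {
    expect_identical(a$recording$streams[[loc]]$acc,
                     b$recording$streams[[loc]]$acc)
    expect_identical(a$recording$streams[[loc]]$gyro,
                     b$recording$streams[[loc]]$gyro)
  }
  expect_identical(a$annotations, b$annotations)
  c_ <- generate_recording(segs, seed = 12)
  expect_false(identical(a$recording$streams$left_ankle$acc,
                         c_$recording$streams$left_ankle$acc))
})

test_that("still-only scenarios are motionless and unannotated", {
  out <- generate_recording(list(seg_still(4), seg_still(3)), seed = 3)
  expect_equal(nrow(out$annotations), 0L)
  mask <- motionless_mask(out$recording)
  expect_gte(mean(mask), 0.99)
})

test_that("walk segments violate the motionless criterion", {
  out <- generate_recording(list(seg_still(2.5), seg_walk(8)), seed = 5)
  mask <- motionless_mask(out$recording)
  walk_idx <- which(out$truth$label == "walk")
  expect_lt(mean(mask[walk_idx]), 0.5)
})

test_that("annotations match the programmed FOG segments exactly", {
  segs <- list(seg_still(2.5), seg_walk(5), seg_fog(3.5), seg_walk(4),
               seg_fog(2))
  out <- generate_recording(segs, seed = 9)
  rate <- out$recording$sampling$rate_hz
  fog_samples <- which(out$truth$label == "fog") - 1L
  ann_samples <- unlist(lapply(seq_len(nrow(out$annotations)), function(i)
    time_to_index(out$annotations$start_s[i], rate):
      (time_to_index(out$annotations$end_s[i], rate) - 1L)))
  expect_identical(sort(fog_samples), sort(as.integer(ann_samples)))
})

test_that("a programmed turn integrates to its angle on the noise-free profile", {
  for (ang in c(90, 180, 360)) {
    gp <- gait_params(noise_sd_gyro = 0, noise_sd_acc = 0)
    out <- generate_recording(list(seg_still(2.5), seg_turn(ang, 4),
                                   seg_walk(2)),
                              gait = gp, seed = 1)
    tr <- attr(out$truth, "turns")
    rate <- out$recording$sampling$rate_hz
    idx <- (time_to_index(tr$start_s, rate) + 1):time_to_index(tr$end_s, rate)
    gv <- out$recording$streams$lower_back$gyro[idx, "v"]
    # remove the deterministic step-frequency wobble by integrating the
    # programmed channel directly: the turn bump is the only net content
    deg <- sum(gv) / rate * 180 / pi
    expect_lt(abs(deg - ang), 2)
  }
})

test_that("walk-segment ankle AP acceleration power sits in the locomotor band", {
  gp <- gait_params(noise_sd_gyro = 0, noise_sd_acc = 0)
  out <- generate_recording(list(seg_still(2.5), seg_walk(8)),
                            gait = gp, seed = 2)
  rate <- out$recording$sampling$rate_hz
  idx <- which(out$truth$label == "walk")
  idx <- idx[257:(256 * 3)]              # interior, away from onset edge
  x <- out$recording$streams$left_ankle$acc[idx, "ap"]
  x <- x - mean(x)
  total <- mean(x^2)
  loco <- band_power(x, c(0.5, 3), rate)
  expect_gte(loco / total, 0.95)
})

test_that("trembling adds power only in the freezing band", {
  gp <- gait_params(noise_sd_gyro = 0, noise_sd_acc = 0)
  base <- generate_recording(list(seg_still(2.5), seg_walk(4), seg_fog(4)),
                             gait = gp,
                             prefog = prefog_params(tremble_amp = 0,
                                                    amp_decay = 1,
                                                    asym_jitter = 0,
                                                    turn_rate = 0),
                             seed = 4)
  trem <- generate_recording(list(seg_still(2.5), seg_walk(4), seg_fog(4)),
                             gait = gp,
                             prefog = prefog_params(tremble_amp = 1,
                                                    amp_decay = 1,
                                                    asym_jitter = 0,
                                                    turn_rate = 0),
                             seed = 4)
  rate <- 128
  # interior of the FOG segment: constant trembling envelope, and 5 Hz
  # falls exactly on a periodogram bin of the 256-sample window
  fi <- which(base$truth$label == "fog")[129:384]
  xb <- base$recording$streams$left_ankle$acc[fi, "ap"]
  xt <- trem$recording$streams$left_ankle$acc[fi, "ap"]
  expect_lt(abs(band_power(xt, c(0.5, 3), rate) -
                  band_power(xb, c(0.5, 3), rate)), 1e-9)
  expect_equal(band_power(xt, c(3, 8), rate) - band_power(xb, c(3, 8), rate),
               0.5, tolerance = 1e-6)
})

test_that("the programmed left-right lag is recovered from noise-free swings", {
  gp <- gait_params(noise_sd_gyro = 0, noise_sd_acc = 0)
  out <- generate_recording(list(seg_still(2.5), seg_walk(8)),
                            gait = gp, seed = 6)
  # a whole number of stride periods, so linear detrending is unbiased
  idx <- which(out$truth$label == "walk")[257:768]
  l <- out$recording$streams$left_ankle$gyro[idx, "ml"]
  r <- out$recording$streams$right_ankle$gyro[idx, "ml"]
  cur <- oracle_xcorr_curve(l, r, round(0.25 * 128), round(1.25 * 128))
  best_lag <- abs(cur$lags[which.max(cur$values)])
  expect_lte(abs(best_lag - round(gp$lr_phase_lag_s * 128)), 1)
})

test_that("FOG onsets preceded by clean walking yield one pre-FOG window each", {
  segs <- list(seg_still(2.5), seg_walk(4), seg_fog(3), seg_walk(4),
               seg_fog(3), seg_walk(4), seg_fog(3), seg_walk(2))
  out <- generate_recording(segs, seed = 13)
  win <- segment_recording(out$recording, out$annotations)
  expect_equal(sum(win$label == "pre_fog"), 3L)
})

test_that("cohort generation is reproducible and rejects duplicate subjects", {
  sc <- default_scenario(n_subjects = 3, n_conditions = 2, seed = 21)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(names(a), names(b))
  expect_identical(a[[1]]$recording$streams$left_ankle$acc,
                   b[[1]]$recording$streams$left_ankle$acc)
  expect_equal(length(a), 6L)
  # different subjects get different streams
  expect_false(identical(a[[1]]$recording$streams$left_ankle$acc,
                         a[[3]]$recording$streams$left_ankle$acc))
  expect_error(scenario_spec(c("S1", "S1"), list(c1 = list(seg_still(2)))),
               "duplicate")
})

test_that("degraded pre-FOG windows shift the features in the expected directions", {
  cs <- cohort_stats(default_scenario(n_subjects = 5, n_conditions = 3,
                                      seed = 31))
  dirs <- setNames(cs$stats$mean_diff, cs$stats$feature)
  expect_gt(dirs[["turning_degrees"]], 0)
  expect_lt(dirs[["lr_xcorr"]], 0)
  expect_lt(dirs[["lr_avg_sd"]], 0)
  expect_lt(dirs[["lowerback_sd"]], 0)
  expect_gt(dirs[["freezing_power"]], 0)
  expect_gt(dirs[["freezing_index"]], 0)
})
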