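# Synthetic multi-sensor gait generator.
#
# Signal model: sum of locomotor harmonics (stride ~1 Hz, step ~2 Hz) with
# per-segment amplitude envelopes, plus Gaussian sensor noise. The pre-FOG
# phase is a linear degradation ramp carved out of the tail of the movement
# segment preceding each FOG episode: swing amplitude decays, a
# freezing-band (3-8 Hz) trembling component rises, left-right phase
# asymmetry grows, and a slow turn builds up (turning triggers freezing).
# FOG episodes themselves have no alternating swing, only trembling. The
# features downstream only sense amplitude, phase and band content, so no
# biomechanical simulation is attempted.

#' Locomotor signal-model parameters
#'
#' @param stride_hz Stride frequency in Hz; steps occur at `2 * stride_hz`.
#'   Must lie in (0.5, 1.5) so all locomotor content stays inside the
#'   0.5-3 Hz locomotor band.
#' @param swing_amp_gyro Mediolateral angular-velocity amplitude of the leg
#'   swing at each ankle (rad/s).
#' @param ap_acc_amp Anteroposterior acceleration amplitude at the step
#'   frequency at the ankles (m/s^2).
#' @param lb_ap_acc_amp,lb_v_acc_amp Lower-back AP / vertical acceleration
#'   amplitudes at the step frequency (m/s^2).
#' @param lr_phase_lag_s Right-vs-left leg lag in seconds; default half a
#'   stride period (perfect alternation).
#' @param noise_sd_gyro,noise_sd_acc White-noise SDs (rad/s, m/s^2).
#' @return A `gait_params` list.
#' @export
gait_params <- function(stride_hz = 1.0, swing_amp_gyro = 2.0,
                        ap_acc_amp = 1.5, lb_ap_acc_amp = 0.8,
                        lb_v_acc_amp = 0.8,
                        lr_phase_lag_s = 0.5 / stride_hz,
                        noise_sd_gyro = 0.05, noise_sd_acc = 0.05) {
  stopifnot(stride_hz > 0.5, stride_hz < 1.5,
            swing_amp_gyro >= 0, ap_acc_amp >= 0,
            lb_ap_acc_amp >= 0, lb_v_acc_amp >= 0,
            lr_phase_lag_s >= 0, noise_sd_gyro >= 0, noise_sd_acc >= 0)
  structure(list(stride_hz = stride_hz, step_hz = 2 * stride_hz,
                 swing_amp_gyro = swing_amp_gyro, ap_acc_amp = ap_acc_amp,
                 lb_ap_acc_amp = lb_ap_acc_amp, lb_v_acc_amp = lb_v_acc_amp,
                 lr_phase_lag_s = lr_phase_lag_s,
                 noise_sd_gyro = noise_sd_gyro, noise_sd_acc = noise_sd_acc),
            class = "gait_params")
}

#' Pre-FOG degradation parameters
#'
#' Controls the linear gait-degradation ramp preceding each (non-abrupt) FOG
#' episode, consistent with the threshold model of freezing: amplitude and
#' symmetry fall while freezing-band trembling and turning rise until onset.
#'
#' @param ramp_s Ramp duration in seconds (>= the 2-s analysis window, so
#'   the pre-FOG window is fully degraded).
#' @param amp_decay Multiplicative swing-amplitude factor reached at onset
#'   (1 = no decay; 0.5 = halved amplitude).
#' @param asym_jitter Extra right-leg phase offset (radians) reached at
#'   onset; breaks left-right alternation.
#' @param tremble_amp Amplitude (m/s^2) of the freezing-band AP-acceleration
#'   trembling component reached at onset (and held during FOG).
#' @param tremble_hz Trembling frequency in Hz, within the 3-8 Hz freezing
#'   band. Default 5.
#' @param turn_rate Peak vertical trunk angular velocity (rad/s) of the turn
#'   that builds up during the ramp (turning is a common FOG trigger).
#' @return A `prefog_params` list.
#' @export
prefog_params <- function(ramp_s = 2, amp_decay = 0.5, asym_jitter = 0.8,
                          tremble_amp = 1.0, tremble_hz = 5,
                          turn_rate = 1.2) {
  stopifnot(ramp_s >= 2, amp_decay > 0, amp_decay <= 1, asym_jitter >= 0,
            tremble_amp >= 0, tremble_hz >= 3, tremble_hz <= 8,
            turn_rate >= 0)
  structure(list(ramp_s = ramp_s, amp_decay = amp_decay,
                 asym_jitter = asym_jitter, tremble_amp = tremble_amp,
                 tremble_hz = tremble_hz, turn_rate = turn_rate),
            class = "prefog_params")
}

#' Scenario segment constructors
#'
#' A condition is an ordered list of segments. `seg_still` is a motionless
#' calibration/rest period; `seg_walk` is steady locomotion; `seg_turn` is
#' locomotion plus a smooth vertical-axis trunk rotation integrating to
#' `angle_deg`; `seg_fog` is a freezing episode (no alternating swing,
#' trembling only). Unless `abrupt = TRUE`, a FOG segment must be preceded
#' by a walk or turn segment at least as long as the degradation ramp, whose
#' tail is converted into the pre-FOG ramp.
#'
#' @param duration_s Segment duration in seconds.
#' @param angle_deg Total turn angle in degrees (sign = direction).
#' @param abrupt If TRUE, the FOG starts with no degradation ramp.
#' @return A segment list with a `type` field.
#' @export
seg_still <- function(duration_s) {
  stopifnot(duration_s > 0)
  list(type = "still", duration_s = duration_s)
}

#' @rdname seg_still
#' @export
seg_walk <- function(duration_s) {
  stopifnot(duration_s > 0)
  list(type = "walk", duration_s = duration_s)
}

#' @rdname seg_still
#' @export
seg_turn <- function(angle_deg, duration_s) {
  stopifnot(is.finite(angle_deg), duration_s > 0)
  list(type = "turn", duration_s = duration_s, angle_deg = angle_deg)
}

#' @rdname seg_still
#' @export
seg_fog <- function(duration_s, abrupt = FALSE) {
  stopifnot(duration_s > 0)
  list(type = "fog", duration_s = duration_s, abrupt = isTRUE(abrupt))
}

# deterministic small hash of a token, for per-(subject, condition) seeds
.token_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (k in v) h <- (h * 131 + k) %% 1000003
  h
}

#' Derive a per-(subject, condition) seed from the master seed
#'
#' Deterministic and spread out, so streams are reproducible yet effectively
#' independent across subjects and conditions.
#'
#' @param master Master integer seed.
#' @param subject_id,condition_id Identifier tokens.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, subject_id, condition_id) {
  h <- (.token_hash(subject_id) * 131071 + .token_hash(condition_id)) %%
    2147483647
  as.integer((master %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483647L
}

.validate_segments <- function(segments, ramp_s, rate_hz) {
  if (!length(segments)) stop("scenario has no segments")
  types <- vapply(segments, `[[`, character(1), "type")
  if (types[1L] != "still" || segments[[1L]]$duration_s < 2)
    stop("every condition must start with a still calibration segment >= 2 s")
  for (i in seq_along(segments)) {
    if (types[i] == "fog" && !segments[[i]]$abrupt) {
      if (i == 1L || !(types[i - 1L] %in% c("walk", "turn")) ||
          segments[[i - 1L]]$duration_s < ramp_s)
        stop(sprintf(
          "FOG segment %d needs a preceding walk/turn segment >= %g s for its pre-FOG ramp (mark abrupt = TRUE to skip)",
          i, ramp_s))
    }
  }
  invisible(types)
}

#' Generate one annotated synthetic recording
#'
#' Deterministic for a fixed seed. Still segments satisfy the motionless
#' criterion (ankle gyro norms < 0.5 rad/s, lower-back acceleration norm
#' within 10% of 9.81 m/s^2) for essentially all samples; walk and turn
#' segments violate it; FOG segments carry trembling but no alternating
#' swing. The returned annotation track marks exactly the programmed FOG
#' segments.
#'
#' @param segments List of segments from the `seg_*` constructors.
#' @param subject_id,condition_id Identifier tokens.
#' @param gait A [gait_params()] set.
#' @param prefog A [prefog_params()] set.
#' @param sampling A [sampling_config()].
#' @param seed Integer seed for the noise streams.
#' @return List with elements `recording`, `annotations` (a [fog_events()]
#'   track) and `truth` (per-sample ground-truth labels
#'   still/walk/turn/pre_fog/fog plus a `turns` attribute with the
#'   programmed turn angles).
#' @export
generate_recording <- function(segments, subject_id = "S01",
                               condition_id = "C01",
                               gait = gait_params(),
                               prefog = prefog_params(),
                               sampling = sampling_config(), seed = 1L) {
  .validate_segments(segments, prefog$ramp_s, sampling$rate_hz)
  rate <- sampling$rate_hz
  nseg <- vapply(segments, function(s) as.integer(round(s$duration_s * rate)),
                 integer(1))
  if (any(nseg < 1L)) stop("segment shorter than one sample")
  n <- sum(nseg)
  starts <- c(0L, cumsum(nseg))           # 0-based segment boundaries
  t <- (seq_len(n) - 1L) / rate
  types <- vapply(segments, `[[`, character(1), "type")

  label <- character(n)
  swing <- numeric(n)      # 1 while locomoting
  u <- numeric(n)          # pre-FOG ramp progress, 0 -> 1 at onset
  fog_ind <- numeric(n)
  turn_w <- numeric(n)     # programmed vertical trunk angular velocity
  turns <- list()
  ramp_n <- as.integer(round(prefog$ramp_s * rate))

  for (i in seq_along(segments)) {
    idx <- (starts[i] + 1L):(starts[i + 1L])
    label[idx] <- types[i]
    if (types[i] %in% c("walk", "turn")) swing[idx] <- 1
    if (types[i] == "turn") {
      Tn <- nseg[i]
      tl <- (seq_len(Tn) - 0.5) / rate     # midpoint phase for clean integral
      Td <- Tn / rate
      a_rad <- segments[[i]]$angle_deg * pi / 180
      turn_w[idx] <- (a_rad / Td) * (1 - cos(2 * pi * tl / Td))
      turns[[length(turns) + 1L]] <-
        data.frame(angle_deg = segments[[i]]$angle_deg,
                   start_s = starts[i] / rate, end_s = starts[i + 1L] / rate)
    }
    if (types[i] == "fog") {
      fog_ind[idx] <- 1
      if (!segments[[i]]$abrupt) {
        ridx <- (starts[i] - ramp_n + 1L):starts[i]
        u[ridx] <- seq_len(ramp_n) / ramp_n
        label[ridx] <- "pre_fog"
      }
    }
  }

  amp_env <- swing * (1 - u * (1 - prefog$amp_decay))
  tremble_env <- prefog$tremble_amp * (u + fog_ind)
  turn_w <- turn_w + u * prefog$turn_rate
  phase <- 2 * pi * gait$stride_hz * t
  lag_phase <- 2 * pi * gait$stride_hz * gait$lr_phase_lag_s
  tremble <- tremble_env * sin(2 * pi * prefog$tremble_hz * t)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed %% 2147483647))
  ng <- function() stats::rnorm(n, 0, gait$noise_sd_gyro)
  na_ <- function() stats::rnorm(n, 0, gait$noise_sd_acc)

  g <- 9.81
  A <- gait$swing_amp_gyro
  left_ml <- amp_env * A * sin(phase) + ng()
  right_ml <- amp_env * A * sin(phase - lag_phase - u * prefog$asym_jitter) +
    ng()
  mk_ankle <- function(ml, leg_off) {
    acc_ap <- amp_env * gait$ap_acc_amp * sin(2 * phase + leg_off) +
      0.3 * amp_env * gait$ap_acc_amp * sin(phase + leg_off / 2) +
      tremble + na_()
    acc <- cbind(ap = acc_ap,
                 ml = 0.4 * amp_env * gait$ap_acc_amp * sin(phase + leg_off) +
                   na_(),
                 v = g + 0.5 * amp_env * sin(2 * phase + leg_off) + na_())
    gyro <- cbind(ap = 0.3 * amp_env * A * sin(2 * phase + leg_off) + ng(),
                  ml = ml,
                  v = 0.2 * amp_env * A * sin(2 * phase + 1 + leg_off) + ng())
    list(acc = acc, gyro = gyro)
  }
  la <- mk_ankle(left_ml, 0)
  ra <- mk_ankle(right_ml, pi)
  lb_acc <- cbind(
    ap = amp_env * gait$lb_ap_acc_amp * sin(2 * phase + 0.3) +
      0.3 * tremble + na_(),
    ml = 0.3 * amp_env * gait$lb_ap_acc_amp * sin(phase) + na_(),
    v = g + amp_env * gait$lb_v_acc_amp * sin(2 * phase) + na_())
  lb_gyro <- cbind(ap = 0.15 * amp_env * sin(phase + 0.5) + ng(),
                   ml = 0.15 * amp_env * sin(phase + 1.0) + ng(),
                   v = turn_w + 0.1 * amp_env * sin(phase) + ng())

  streams <- list(sensor_stream("left_ankle", la$acc, la$gyro),
                  sensor_stream("right_ankle", ra$acc, ra$gyro),
                  sensor_stream("lower_back", lb_acc, lb_gyro))
  still1 <- c(0, nseg[1L] / rate)
  rec <- recording(subject_id, condition_id, streams, sampling, still1)

  fog_i <- which(types == "fog")
  ann <- fog_events(starts[fog_i] / rate, starts[fog_i + 1L] / rate,
                    duration_s = n / rate)
  truth <- data.frame(sample = seq_len(n) - 1L, t_s = t, label = label,
                      stringsAsFactors = FALSE)
  attr(truth, "turns") <- if (length(turns)) do.call(rbind, turns) else
    data.frame(angle_deg = numeric(), start_s = numeric(), end_s = numeric())
  list(recording = rec, annotations = ann, truth = truth)
}

#' Build a cohort scenario specification
#'
#' @param subjects Character vector of unique subject tokens (>= 2 for a
#'   meaningful leave-one-subject-out evaluation downstream).
#' @param conditions Either a named list of segment lists (shared across
#'   subjects) or a function `f(subject_id, condition_id, seed)` returning a
#'   segment list, for per-subject/condition variation. If a function,
#'   `condition_ids` names the conditions.
#' @param seed Master integer seed; per-(subject, condition) seeds are
#'   derived from it by token hashing.
#' @param gait,prefog Parameter sets; `gait` may also be a function
#'   `f(subject_id, seed)` returning per-subject parameters.
#' @param condition_ids Condition tokens when `conditions` is a function.
#' @param sampling A [sampling_config()].
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(subjects, conditions, seed = 1L,
                          gait = gait_params(), prefog = prefog_params(),
                          condition_ids = NULL,
                          sampling = sampling_config()) {
  stopifnot(is.character(subjects), length(subjects) >= 1L)
  if (anyDuplicated(subjects))
    stop("duplicate subject token(s): ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  if (is.function(conditions)) {
    if (is.null(condition_ids)) stop("condition_ids required with a builder")
  } else {
    stopifnot(is.list(conditions), !is.null(names(conditions)))
    condition_ids <- names(conditions)
  }
  structure(list(subjects = subjects, conditions = conditions,
                 condition_ids = condition_ids, seed = seed, gait = gait,
                 prefog = prefog, sampling = sampling),
            class = "scenario_spec")
}

#' Generate all recordings of a cohort scenario
#'
#' @param spec A [scenario_spec()].
#' @return Named list (one element per subject x condition, named
#'   `"subject.condition"`) of `generate_recording()` outputs.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- list()
  for (subj in spec$subjects) {
    gp <- if (is.function(spec$gait))
      spec$gait(subj, derive_seed(spec$seed, subj, ".gait")) else spec$gait
    for (cond in spec$condition_ids) {
      sd_ <- derive_seed(spec$seed, subj, cond)
      segs <- if (is.function(spec$conditions))
        spec$conditions(subj, cond, sd_) else spec$conditions[[cond]]
      out[[paste(subj, cond, sep = ".")]] <-
        generate_recording(segs, subj, cond, gait = gp, prefog = spec$prefog,
                           sampling = spec$sampling, seed = sd_)
    }
  }
  out
}

# segment builder used by the stock scenarios: still, walk, turn, walk,
# then n_fog x (fog, walk); durations drawn from the local RNG. In
# null_mode an abrupt FOG separates the calibration stillness from the
# first walk, so every gait window is pure walking and the gait vs pre-FOG
# comparison is exchangeable under the null (no turns either).
.build_condition <- function(seed, n_fog = 2, with_turns = TRUE,
                             null_mode = FALSE) {
  set.seed(seed)
  r <- function(a, b) stats::runif(1, a, b)
  segs <- list(seg_still(r(2.5, 3.5)))
  if (null_mode) segs <- c(segs, list(seg_fog(2, abrupt = TRUE)))
  segs <- c(segs, list(seg_walk(r(6, 9))))
  if (with_turns)
    segs <- c(segs, list(seg_turn(sample(c(-1, 1), 1) * r(120, 360),
                                  r(3, 4)),
                         seg_walk(r(4, 7))))
  for (k in seq_len(n_fog))
    segs <- c(segs, list(seg_fog(r(3, 5)), seg_walk(r(4, 7))))
  segs
}

# mild per-subject gait variation: stride frequency and amplitudes differ
# across subjects, which is what makes leave-one-subject-out non-trivial
.subject_gait <- function(subject_id, seed, variability = 0.15) {
  set.seed(seed)
  j <- function() stats::runif(1, 1 - variability, 1 + variability)
  stride <- min(1.35, max(0.7, 1.0 * j()))
  gait_params(stride_hz = stride, swing_amp_gyro = 2.0 * j(),
              ap_acc_amp = 1.5 * j(), lb_ap_acc_amp = 0.8 * j(),
              lb_v_acc_amp = 0.8 * j())
}

#' Stock cohort scenarios
#'
#' `default_scenario()` emulates a FOG-provoking multi-condition protocol:
#' each condition starts with a still calibration period, then walking with
#' a turn and two FOG episodes, each preceded by a 2-s degradation ramp
#' (defaults of [prefog_params()]). With 10 subjects x 5 conditions it
#' yields ~50 (subject, condition) paired samples, each with both gait and
#' pre-FOG windows. `null_scenario()` disables every degradation channel
#' (no amplitude decay, no trembling, no asymmetry, no pre-FOG turn) and
#' removes turn segments, so windows ahead of FOG onsets are statistically
#' identical to ordinary gait windows — the null distribution for type-I
#' error checks.
#'
#' @param n_subjects,n_conditions Cohort dimensions.
#' @param seed Master seed.
#' @param prefog Degradation parameters (ignored by `null_scenario`).
#' @param subject_variability Fractional range of per-subject gait-parameter
#'   variation.
#' @return A [scenario_spec()].
#' @export
default_scenario <- function(n_subjects = 10, n_conditions = 5, seed = 1L,
                             prefog = prefog_params(),
                             subject_variability = 0.15) {
  scenario_spec(
    subjects = sprintf("S%02d", seq_len(n_subjects)),
    conditions = function(subj, cond, sd_) .build_condition(sd_, n_fog = 2),
    condition_ids = sprintf("C%d", seq_len(n_conditions)),
    seed = seed,
    gait = function(subj, sd_) .subject_gait(subj, sd_, subject_variability),
    prefog = prefog)
}

#' @rdname default_scenario
#' @export
null_scenario <- function(n_subjects = 6, n_conditions = 2, seed = 1L,
                          subject_variability = 0.15) {
  scenario_spec(
    subjects = sprintf("S%02d", seq_len(n_subjects)),
    conditions = function(subj, cond, sd_)
      .build_condition(sd_, n_fog = 2, with_turns = FALSE,
                       null_mode = TRUE),
    condition_ids = sprintf("C%d", seq_len(n_conditions)),
    seed = seed,
    gait = function(subj, sd_) .subject_gait(subj, sd_, subject_variability),
    prefog = prefog_params(amp_decay = 1, asym_jitter = 0, tremble_amp = 0,
                           turn_rate = 0))
}
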