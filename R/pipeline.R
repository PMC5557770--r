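# End-to-end orchestration: cohort generation/segmentation/feature
# extraction -> paired statistics -> feature selection -> LOSO evaluation,
# with optional on-disk artifacts.

#' Pipeline configuration
#'
#' Gathers every tunable of the analysis with its default: sampling (128 Hz,
#' 2-s windows), motion check (0.5 rad/s, 10% acceleration tolerance, 50%
#' motionless fraction), frequency bands (0.5-3 / 3-8 Hz), cross-correlation
#' lag range (0.25-1.25 s), significance level 0.05, empirical LDA priors,
#' correlation guard 0.9, and the master seed.
#'
#' @param seed Master seed for the synthetic cohort.
#' @param sampling A [sampling_config()].
#' @param motion A [motion_params()].
#' @param bands A [band_definition()].
#' @param xcorr An [xcorr_params()].
#' @param alpha Significance level for the paired tests.
#' @param priors LDA priors mode, `"empirical"` or `"equal"`.
#' @param correlation_guard Feature-selection collinearity guard.
#' @param n_select Number of classifier features.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sampling = sampling_config(),
                            motion = motion_params(),
                            bands = band_definition(),
                            xcorr = xcorr_params(), alpha = 0.05,
                            priors = "empirical", correlation_guard = 0.9,
                            n_select = 3) {
  structure(list(seed = seed, sampling = sampling, motion = motion,
                 bands = bands, xcorr = xcorr, alpha = alpha,
                 priors = priors, correlation_guard = correlation_guard,
                 n_select = n_select),
            class = "pipeline_config")
}

# order-insensitive fingerprint of the configuration, recorded in the run
# manifest so artifacts are traceable to their settings
.config_fingerprint <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(txt)
  h <- 5381
  for (k in v) h <- (h * 33 + k) %% 4294967291
  sprintf("%08x", h)
}

#' Segment and featurize a set of annotated recordings
#'
#' The shared front half of the pipeline, usable on any list of
#' recording/annotation pairs (synthetic or read from disk).
#'
#' @param entries List of `list(recording =, annotations =)` pairs.
#' @param config A [pipeline_config()].
#' @return List with combined `windows` and `features` tables.
#' @export
analyze_recordings <- function(entries, config = pipeline_config()) {
  win <- list(); feat <- list()
  for (e in entries) {
    rec <- e$recording
    wdf <- segment_recording(rec, e$annotations, config$sampling,
                             config$motion)
    win[[length(win) + 1L]] <- wdf
    feat[[length(feat) + 1L]] <-
      extract_features(wdf, rec, config$bands, config$xcorr)
  }
  list(windows = do.call(rbind, win), features = do.call(rbind, feat))
}

#' Run the full pipeline on a cohort scenario
#'
#' Generates the cohort, segments every recording, extracts features,
#' builds the paired samples, runs the eight-feature paired analysis,
#' selects the classifier features, and evaluates leave-one-subject-out.
#' Deterministic given the scenario seed. If the cohort yields no pre-FOG
#' windows the statistical and classification stages are skipped with a
#' message and the partial result returned.
#'
#' @param scenario A [scenario_spec()] (e.g. [default_scenario()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, windows/features/pairs/
#'   stats/eval CSV tables plus a JSON run manifest are written there.
#' @return List with `windows`, `features`, `pairs`, `stats`, `selected`,
#'   `eval` (see [loso_evaluate()]) and a `summary` of window/pair counts.
#' @export
run_pipeline <- function(scenario, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  cohort <- generate_cohort(scenario)
  fr <- analyze_recordings(cohort, config)
  windows <- fr$windows
  features <- fr$features
  pairs <- build_paired_samples(features)
  summary <- list(
    n_recordings = length(cohort),
    n_gait_windows = sum(windows$label == "gait"),
    n_prefog_windows = sum(windows$label == "pre_fog"),
    n_discarded_windows = sum(startsWith(windows$label, "discarded")),
    n_paired_samples = nrow(pairs))
  res <- list(windows = windows, features = features, pairs = pairs,
              stats = NULL, selected = NULL, eval = NULL, summary = summary)
  if (summary$n_prefog_windows == 0L || nrow(pairs) < 2L) {
    message("no (or too few) pre-FOG windows: skipping statistics and ",
            "classification stages")
    return(.write_run(res, config, out_dir))
  }
  res$stats <- run_group_analysis(pairs, config$alpha)
  pool <- features[features$label == "gait", feature_names(), drop = FALSE]
  res$selected <- select_features(res$stats, pool, config$n_select,
                                  config$correlation_guard)
  # train/test on the windows of the selected conditions only (those with
  # both gait and pre-FOG)
  key <- paste(features$subject, features$condition)
  sel_cond <- paste(pairs$subject, pairs$condition)
  res$eval <- loso_evaluate(features[key %in% sel_cond, , drop = FALSE],
                            res$selected, priors = config$priors)
  .write_run(res, config, out_dir)
}

.write_run <- function(res, config, out_dir) {
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_windows(res$windows, file.path(out_dir, "windows.csv"))
  write_features(res$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(data.table::as.data.table(res$pairs),
                     file.path(out_dir, "pairs.csv"))
  if (!is.null(res$stats))
    data.table::fwrite(data.table::as.data.table(res$stats),
                       file.path(out_dir, "stats.csv"))
  if (!is.null(res$eval))
    write_results(res$eval$per_subject, file.path(out_dir, "eval.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("prefog")),
    seed = config$seed, config_fingerprint = .config_fingerprint(config),
    alpha = config$alpha, priors = config$priors,
    selected_features = res$selected, summary = res$summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}
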