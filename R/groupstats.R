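# Paired per-(subject, condition) statistics: feature averaging into gait /
# pre-FOG pairs, paired t-tests, and Benjamini-Yekutieli multiplicity
# correction across the eight-feature family.

#' Build per-(subject, condition) paired samples
#'
#' For every (subject, condition) group that has at least one gait AND at
#' least one pre-FOG window, averages the feature values within each class,
#' yielding one paired observation per group. Averaging absorbs the strong
#' imbalance between gait and pre-FOG window counts. Groups lacking either
#' class are excluded.
#'
#' @param features Feature data.frame from [extract_features()] (possibly
#'   row-bound across recordings), with `subject`, `condition`, `label` and
#'   the eight [feature_names()] columns.
#' @return Data.frame with one row per selected (subject, condition):
#'   `subject, condition, n_gait, n_prefog`, then `gait_<feature>` and
#'   `prefog_<feature>` mean columns.
#' @export
build_paired_samples <- function(features) {
  fn <- feature_names()
  stopifnot(all(c("subject", "condition", "label", fn) %in% names(features)))
  dt <- data.table::as.data.table(features)
  dt <- dt[dt$label %in% c("gait", "pre_fog"), ]
  if (nrow(dt) == 0L) return(.empty_pairs())
  label <- NULL  # appease R CMD check
  agg <- dt[, c(list(n = .N), lapply(.SD, mean)),
            by = c("subject", "condition", "label"), .SDcols = fn]
  g <- agg[agg$label == "gait", ]
  p <- agg[agg$label == "pre_fog", ]
  m <- merge(g, p, by = c("subject", "condition"), suffixes = c(".g", ".p"))
  if (nrow(m) == 0L) return(.empty_pairs())
  out <- data.frame(subject = m$subject, condition = m$condition,
                    n_gait = m$n.g, n_prefog = m$n.p,
                    stringsAsFactors = FALSE)
  for (f in fn) out[[paste0("gait_", f)]] <- m[[paste0(f, ".g")]]
  for (f in fn) out[[paste0("prefog_", f)]] <- m[[paste0(f, ".p")]]
  out[order(out$subject, out$condition), , drop = FALSE]
}

.empty_pairs <- function() {
  out <- data.frame(subject = character(), condition = character(),
                    n_gait = integer(), n_prefog = integer(),
                    stringsAsFactors = FALSE)
  for (f in feature_names()) out[[paste0("gait_", f)]] <- numeric()
  for (f in feature_names()) out[[paste0("prefog_", f)]] <- numeric()
  out
}

#' Paired t-test between gait and pre-FOG means
#'
#' Two-sided paired t-test on the per-(subject, condition) differences
#' (pre-FOG minus gait), df = n - 1. A zero-variance difference vector is a
#' degenerate case: the statistic is undefined and reported as NA with
#' `degenerate = TRUE`, never silently coerced.
#'
#' @param gait,prefog Equal-length numeric vectors of paired means.
#' @return List with `n`, `t_stat`, `df`, `p_value`, `mean_diff`
#'   (pre-FOG minus gait) and `degenerate`.
#' @export
paired_t_test <- function(gait, prefog) {
  n <- length(gait)
  if (length(prefog) != n) stop("paired samples differ in length")
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- prefog - gait
  if (stats::sd(d) == 0)
    return(list(n = n, t_stat = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  ht <- stats::t.test(prefog, gait, paired = TRUE)
  list(n = n, t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence,
#' with correction factor `c(m) = sum(1/i, i = 1..m)`. Implemented via
#' [stats::p.adjust()]; significance is decided on adjusted p <= alpha.
#'
#' @param p Numeric p-values in `[0, 1]` (NAs allowed and propagated).
#' @param alpha Significance level, default 0.05.
#' @return List with `p_adjusted` and logical `significant`.
#' @export
benjamini_yekutieli <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BY")
  list(p_adjusted = adj, significant = !is.na(adj) & adj <= alpha)
}

#' Run the eight-feature paired analysis
#'
#' One paired t-test per feature on the per-(subject, condition) gait vs
#' pre-FOG means, then Benjamini-Yekutieli correction across exactly the
#' eight-feature family (partial families are refused). The sign of
#' `mean_diff` gives the direction of the pre-FOG shift.
#'
#' @param pairs Paired-sample data.frame from [build_paired_samples()].
#' @param alpha Significance level applied to the adjusted p-values.
#' @return Data.frame with one row per feature: `feature, n_pairs, t_stat,
#'   p_value, p_adjusted, significant, mean_diff, degenerate`.
#' @export
run_group_analysis <- function(pairs, alpha = 0.05) {
  fn <- feature_names()
  need <- c(paste0("gait_", fn), paste0("prefog_", fn))
  missing <- setdiff(need, names(pairs))
  if (length(missing))
    stop("pairs table is missing column(s): ",
         paste(missing, collapse = ", "),
         " (the eight-feature family must be tested together)")
  if (nrow(pairs) < 2L) stop("need at least 2 paired samples")
  res <- lapply(fn, function(f)
    paired_t_test(pairs[[paste0("gait_", f)]],
                  pairs[[paste0("prefog_", f)]]))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  by <- benjamini_yekutieli(p, alpha)
  data.frame(feature = fn,
             n_pairs = vapply(res, `[[`, numeric(1), "n"),
             t_stat = vapply(res, `[[`, numeric(1), "t_stat"),
             p_value = p,
             p_adjusted = by$p_adjusted,
             significant = by$significant,
             mean_diff = vapply(res, `[[`, numeric(1), "mean_diff"),
             degenerate = vapply(res, `[[`, logical(1), "degenerate"),
             stringsAsFactors = FALSE)
}
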