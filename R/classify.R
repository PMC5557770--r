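# Three-feature linear-discriminant pre-FOG probability model with
# leave-one-subject-out evaluation, ROC/AUC, and Youden-optimal thresholds.

#' Select the classifier features
#'
#' Takes features in ascending order of their paired-test p-value; a
#' candidate whose absolute Pearson correlation with an already-selected
#' feature (computed on the supplied window pool, conventionally the gait
#' windows) exceeds the guard is skipped in favor of the next-ranked
#' feature. Highly collinear inputs add no discriminative information to a
#' linear model and destabilize the pooled covariance.
#'
#' @param stats Result table from [run_group_analysis()] (`feature` and
#'   `p_value` columns used; NA p-values are inadmissible).
#' @param pool Data.frame/matrix of window feature values on which pairwise
#'   correlations are computed; must contain every feature column.
#' @param n_select Number of features to return (default 3).
#' @param correlation_guard Absolute-correlation threshold (default 0.9).
#' @return Character vector of `n_select` feature names.
#' @export
select_features <- function(stats, pool, n_select = 3,
                            correlation_guard = 0.9) {
  stopifnot(all(c("feature", "p_value") %in% names(stats)))
  ranked <- stats$feature[order(stats$p_value)]
  ranked <- ranked[!is.na(stats$p_value[order(stats$p_value)])]
  sel <- character(0)
  for (f in ranked) {
    if (length(sel) >= n_select) break
    r <- if (length(sel))
      suppressWarnings(abs(stats::cor(as.data.frame(pool)[[f]],
                                      as.data.frame(pool)[sel])))
    else 0
    if (all(is.na(r)) || all(r <= correlation_guard, na.rm = TRUE))
      sel <- c(sel, f)
  }
  if (length(sel) < n_select)
    stop(sprintf(
      "only %d admissible feature(s) under correlation guard %.2f",
      length(sel), correlation_guard))
  sel
}

#' Fit a two-class linear discriminant model
#'
#' Gaussian classes with a shared (pooled within-class) covariance,
#' regularized by a ridge of `ridge * trace / d` on the diagonal for
#' numerical safety on near-collinear features. Priors are either the
#' training class frequencies (`"empirical"`) or `"equal"`.
#'
#' @param x Numeric matrix (or data.frame) of training features, one row
#'   per window.
#' @param y Class labels, coercible to a factor with levels `gait` and
#'   `pre_fog`.
#' @param priors `"empirical"` or `"equal"`.
#' @param ridge Ridge fraction applied to the pooled covariance diagonal.
#' @return A `prefog_lda` model.
#' @export
fit_lda <- function(x, y, priors = c("empirical", "equal"), ridge = 1e-6) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y, levels = c("gait", "pre_fog"))
  if (anyNA(y)) stop("labels must be 'gait' or 'pre_fog'")
  counts <- table(y)
  if (any(counts < 2L))
    stop("need at least 2 training windows per class, got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  d <- ncol(x)
  means <- rbind(gait = colMeans(x[y == "gait", , drop = FALSE]),
                 pre_fog = colMeans(x[y == "pre_fog", , drop = FALSE]))
  sg <- stats::cov(x[y == "gait", , drop = FALSE])
  sp <- stats::cov(x[y == "pre_fog", , drop = FALSE])
  pooled <- ((counts[["gait"]] - 1L) * sg + (counts[["pre_fog"]] - 1L) * sp) /
    (sum(counts) - 2L)
  pooled <- pooled + diag(ridge * sum(diag(pooled)) / d, d)
  ch <- tryCatch(chol(pooled), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled covariance is singular even after regularization")
  pr <- if (priors == "empirical") as.numeric(counts) / sum(counts)
        else c(0.5, 0.5)
  names(pr) <- c("gait", "pre_fog")
  structure(list(feature_names = colnames(x), classes = c("gait", "pre_fog"),
                 means = means, pooled_cov = pooled, chol = ch, priors = pr),
            class = "prefog_lda")
}

#' @export
print.prefog_lda <- function(x, ...) {
  cat("<prefog_lda>", length(x$feature_names), "features:",
      paste(x$feature_names, collapse = ", "), "\n")
  cat("  priors:", sprintf("gait %.3f, pre_fog %.3f", x$priors[1L],
                           x$priors[2L]), "\n")
  invisible(x)
}

#' Posterior probability of pre-FOG
#'
#' Gaussian class-conditional posterior under the shared covariance:
#' continuous and monotone along the discriminant axis, and invariant under
#' any invertible affine map applied consistently to training and test
#' features.
#'
#' @param model A `prefog_lda` from [fit_lda()].
#' @param x Feature vector or matrix (columns in the model's feature
#'   order).
#' @return Numeric vector of pre-FOG posterior probabilities in `[0, 1]`.
#' @export
posterior_prefog <- function(model, x) {
  stopifnot(inherits(model, "prefog_lda"))
  x <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$feature_names))
    stop(sprintf("expected %d feature columns, got %d",
                 length(model$feature_names), ncol(x)))
  lg <- -0.5 * stats::mahalanobis(x, model$means["gait", ],
                                  model$pooled_cov) +
    log(model$priors[["gait"]])
  lp <- -0.5 * stats::mahalanobis(x, model$means["pre_fog", ],
                                  model$pooled_cov) +
    log(model$priors[["pre_fog"]])
  1 / (1 + exp(lg - lp))
}

.as_prefog_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("gait", "pre_fog"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  labels == "pre_fog"
}

#' Area under the ROC curve
#'
#' Computed in the rank (Mann-Whitney) form: the probability that a random
#' pre-FOG score exceeds a random gait score, with ties counted 1/2.
#'
#' @param scores Numeric classifier scores (higher = more pre-FOG-like).
#' @param labels Class labels (`gait`/`pre_fog`, or logical with TRUE =
#'   pre-FOG).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_prefog_logical(labels)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Youden-optimal operating point
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over thresholds
#' taken at the midpoints of consecutive distinct scores, classifying
#' pre-FOG when score > threshold. Ties in J are broken toward higher
#' specificity (then toward the higher threshold).
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity` and
#'   `youden_j`.
#' @export
youden_optimal <- function(scores, labels) {
  pos <- .as_prefog_logical(labels)
  if (!any(pos) || all(pos))
    stop("Youden threshold undefined: both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else s
  best <- NULL
  for (th in cand) {
    sens <- mean(scores[pos] > th)
    spec <- mean(scores[!pos] <= th)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && th > best$threshold))))
      best <- list(threshold = th, sensitivity = sens, specificity = spec,
                   youden_j = j)
  }
  best
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject, fits the discriminant model on all remaining
#' subjects' windows, scores the held-out subject's windows, and reports
#' the per-subject AUC plus the Youden-optimal sensitivity/specificity/
#' threshold computed on that subject's own scores (an evaluation
#' statistic characterizing the subject's attainable operating point, not
#' a deployable rule). Subjects whose test windows contain a single class
#' get an NA row (with a warning) and are excluded from the mean.
#'
#' @param features Feature data.frame with `subject`, `label`
#'   (`gait`/`pre_fog`) and the classifier feature columns.
#' @param selected Character vector of feature names to use.
#' @param priors,ridge Passed to [fit_lda()].
#' @return List with `per_subject` (one `EvalRow` per subject:
#'   `subject_id, auc, sensitivity, specificity, threshold`), `mean` (the
#'   [summarize_eval()] row) and `scores` (per-window probability table).
#' @export
loso_evaluate <- function(features, selected, priors = "empirical",
                          ridge = 1e-6) {
  stopifnot(all(c("subject", "label", selected) %in% names(features)))
  subjects <- unique(features$subject)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  rows <- vector("list", length(subjects))
  traces <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test <- features[features$subject == s, , drop = FALSE]
    train <- features[features$subject != s, , drop = FALSE]
    stopifnot(!any(train$subject == s))  # no leak by construction
    model <- fit_lda(train[, selected, drop = FALSE], train$label,
                     priors = priors, ridge = ridge)
    prob <- posterior_prefog(model, test[, selected, drop = FALSE])
    tr <- data.frame(subject = s, label = test$label, probability = prob,
                     stringsAsFactors = FALSE)
    for (col in c("condition", "start_sample"))
      if (col %in% names(test)) tr[[col]] <- test[[col]]
    traces[[i]] <- tr
    if (length(unique(test$label)) < 2L) {
      warning("subject ", s,
              " has a single class in its test windows; AUC undefined")
      rows[[i]] <- data.frame(subject_id = s, auc = NA_real_,
                              sensitivity = NA_real_,
                              specificity = NA_real_, threshold = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    auc <- roc_auc(prob, test$label)
    yo <- youden_optimal(prob, test$label)
    rows[[i]] <- data.frame(subject_id = s, auc = auc,
                            sensitivity = yo$sensitivity,
                            specificity = yo$specificity,
                            threshold = yo$threshold,
                            stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean = summarize_eval(per_subject, digits = 6),
       scores = do.call(rbind, traces))
}
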