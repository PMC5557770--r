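test_that("feature selection takes lowest p-values with a collinearity guard", {
  stats <- data.frame(
    feature = feature_names(),
    p_value = c(0.004, 0.001, 0.002, 0.3, 0.5, 0.6, 0.7, 0.003))
  # ranks: lr_xcorr (.001) < lr_avg_sd (.002) < freezing_index (.003)
  #        < turning_degrees (.004)
  set.seed(1)
  n <- 200
  base <- rnorm(n)
  pool <- data.frame(turning_degrees = rnorm(n), lr_xcorr = base,
                     lr_avg_sd = base + rnorm(n, sd = 0.05),  # r ~ 0.95+
                     lr_diff_sd = rnorm(n), lowerback_sd = rnorm(n),
                     locomotor_power = rnorm(n), freezing_power = rnorm(n),
                     freezing_index = rnorm(n))
  stopifnot(abs(cor(pool$lr_xcorr, pool$lr_avg_sd)) > 0.9)
  sel <- select_features(stats, pool)
  expect_equal(sel, c("lr_xcorr", "freezing_index", "turning_degrees"))

  # nothing collinear: simply the 3 lowest p
  pool2 <- pool; pool2$lr_avg_sd <- rnorm(n)
  expect_equal(select_features(stats, pool2),
               c("lr_xcorr", "lr_avg_sd", "freezing_index"))

  # everything collinear with the best: error
  pool3 <- pool
  for (f in feature_names()) pool3[[f]] <- base + rnorm(n, sd = 0.01)
  expect_error(select_features(stats, pool3), "admissible")
})

test_that("the discriminant midpoint has posterior one half", {
  set.seed(2)
  x <- matrix(c(rnorm(200, -1), rnorm(200, 1)), ncol = 1)
  y <- rep(c("gait", "pre_fog"), each = 200)
  m <- fit_lda(x, y, priors = "equal")
  mid <- mean(m$means)
  expect_equal(posterior_prefog(m, mid), 0.5, tolerance = 1e-6,
               ignore_attr = TRUE)
  far <- posterior_prefog(m, m$means["pre_fog", ] + 10)
  expect_gt(far, 0.999)
})

test_that("LDA recovers the generating Gaussian parameters", {
  set.seed(3)
  n <- 10000
  mu_g <- c(0, 0, 0); mu_p <- c(1, -1, 0.5)
  x <- rbind(matrix(rnorm(3 * n), ncol = 3) + rep(mu_g, each = n),
             matrix(rnorm(3 * n), ncol = 3) + rep(mu_p, each = n))
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("gait", "pre_fog"), each = n)
  m <- fit_lda(x, y)
  se <- 1 / sqrt(n)
  expect_true(all(abs(m$means["gait", ] - mu_g) < 3 * se))
  expect_true(all(abs(m$means["pre_fog", ] - mu_p) < 3 * se))
  expect_true(all(abs(m$pooled_cov - diag(3)) < 0.05))
  expect_equal(as.numeric(m$priors), c(0.5, 0.5))
})

test_that("posteriors agree with a brute-force density ratio", {
  set.seed(4)
  x <- matrix(rnorm(600), ncol = 3)
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("gait", "pre_fog"), each = 100)
  x[y == "pre_fog", ] <- x[y == "pre_fog", ] + 0.8
  m <- fit_lda(x, y)
  dens <- function(v, mu, S)
    exp(-0.5 * drop(t(v - mu) %*% solve(S) %*% (v - mu))) /
      sqrt((2 * pi)^3 * det(S))
  pts <- matrix(rnorm(300), ncol = 3)
  p_impl <- posterior_prefog(m, pts)
  p_ref <- apply(pts, 1, function(v) {
    dg <- dens(v, m$means["gait", ], m$pooled_cov) * m$priors[["gait"]]
    dp <- dens(v, m$means["pre_fog", ], m$pooled_cov) *
      m$priors[["pre_fog"]]
    dp / (dg + dp)
  })
  expect_lt(max(abs(p_impl - p_ref)), 1e-10)
})

test_that("posteriors match MASS::lda on a well-conditioned fixture", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- matrix(rnorm(400), ncol = 2)
  colnames(x) <- c("a", "b")
  y <- rep(c("gait", "pre_fog"), each = 100)
  x[y == "pre_fog", ] <- x[y == "pre_fog", ] + 1
  m <- fit_lda(x, y, ridge = 0)
  ref <- MASS::lda(x, grouping = factor(y))
  p_ref <- predict(ref, x)$posterior[, "pre_fog"]
  expect_lt(max(abs(posterior_prefog(m, x) - p_ref)), 1e-6)
})

test_that("posteriors are invariant under affine feature maps", {
  set.seed(6)
  x <- matrix(rnorm(600), ncol = 3)
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("gait", "pre_fog"), each = 100)
  x[y == "pre_fog", ] <- x[y == "pre_fog", ] + 0.5
  A <- matrix(c(2, 0.3, 0, 0.1, -1, 0.2, 0, 0.5, 3), 3, 3)
  b <- c(10, -5, 2)
  xt <- sweep(x %*% A, 2, b, "+")
  colnames(xt) <- colnames(x)
  p1 <- posterior_prefog(fit_lda(x, y, ridge = 0), x)
  p2 <- posterior_prefog(fit_lda(xt, y, ridge = 0), xt)
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("AUC equals Mann-Whitney pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_identical(roc_auc(scores, pos), oracle_auc(scores, pos))
  }
})

test_that("AUC agrees with the trapezoidal ROC area from pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(60)
  pos <- rep(c(TRUE, FALSE), 30)
  scores[pos] <- scores[pos] + 1
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, pos), ref, tolerance = 1e-12)
})

test_that("the Youden threshold maximizes J with the documented tie-break", {
  sep <- youden_optimal(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_gt(sep$threshold, 0.2); expect_lt(sep$threshold, 0.8)

  tie <- youden_optimal(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tie$youden_j, 0.5)
  expect_equal(tie$threshold, 0.7)       # higher-specificity side
  expect_equal(tie$specificity, 1)

  # shift invariance
  sh <- youden_optimal(c(0.9, 0.4, 0.5, 0.1) + 3,
                       c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sh$threshold, 3.7)
  expect_equal(sh$youden_j, 0.5)

  set.seed(9)
  for (i in 1:20) {
    scores <- round(runif(20), 2)
    pos <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(pos) || all(pos)) next
    got <- youden_optimal(scores, pos)
    ref <- oracle_youden(scores, pos)
    expect_equal(got$threshold, ref$th)
    expect_equal(got$youden_j, ref$j, tolerance = 1e-9)
  }
})

test_that("LOSO evaluation separates identical separable subjects perfectly", {
  set.seed(10)
  mk_subj <- function(s) {
    n <- 30
    df <- data.frame(subject = s,
                     label = rep(c("gait", "pre_fog"), each = n))
    df$f1 <- c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1))
    df$f2 <- c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1))
    df$f3 <- rnorm(2 * n)
    df
  }
  feats <- rbind(mk_subj("A"), mk_subj("B"))
  ev <- loso_evaluate(feats, c("f1", "f2", "f3"))
  expect_equal(ev$per_subject$auc, c(1, 1))
  expect_equal(ev$mean$auc, 1)
  expect_equal(ev$mean$sensitivity, 1)

  # a subject with one class gets an NA row and is excluded from the mean
  one_class <- mk_subj("C")
  one_class <- one_class[one_class$label == "gait", ]
  expect_warning(ev2 <- loso_evaluate(rbind(feats, one_class),
                                      c("f1", "f2", "f3")),
                 "single class")
  expect_true(is.na(ev2$per_subject$auc[ev2$per_subject$subject_id == "C"]))
  expect_equal(ev2$mean$auc, 1)
  expect_error(loso_evaluate(mk_subj("A"), c("f1", "f2", "f3")),
               "at least 2 subjects")
})
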