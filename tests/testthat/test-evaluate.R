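# independent one-vs-rest oracle: expand the confusion matrix into label
# pairs and count TP/FP/TN/FN directly
oracle_metrics <- function(cm, class_k) {
  lv <- c("B", "T", "TB")
  truth <- rep(rep(lv, each = 3), times = as.vector(t(cm)))
  pred <- rep(rep(lv, times = 3), times = as.vector(t(cm)))
  pos_t <- truth == lv[class_k]; pos_p <- pred == lv[class_k]
  TP <- sum(pos_t & pos_p); FN <- sum(pos_t & !pos_p)
  FP <- sum(!pos_t & pos_p); TN <- sum(!pos_t & !pos_p)
  c(sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
    ppv = TP / (TP + FP), npv = TN / (TN + FN),
    prevalence_predicted = (TP + FP) / length(truth),
    prevalence_true = (TP + FN) / length(truth),
    balanced_accuracy = (TP / (TP + FN) + TN / (TN + FP)) / 2)
}

test_that("metrics agree with a brute-force counter on random matrices", {
  set.seed(12)
  worst <- 0
  for (i in 1:1000) {
    cm <- matrix(rpois(9, 8), 3, dimnames = list(c("B", "T", "TB"),
                                                 c("B", "T", "TB")))
    if (sum(cm) == 0) next
    rep_ <- suppressWarnings(compute_metrics(cm))
    for (k in 1:3) {
      o <- oracle_metrics(cm, k)
      d <- abs(vapply(names(o), function(m) rep_[[m]][k], 0) - o)
      worst <- max(worst, d[is.finite(d)])
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("metric report satisfies its internal identities", {
  set.seed(33)
  cm <- matrix(rpois(9, 20) + 1, 3, dimnames = list(c("B", "T", "TB"),
                                                    c("B", "T", "TB")))
  rep_ <- compute_metrics(cm)
  expect_equal(rep_$precision, rep_$ppv)
  expect_equal(rep_$balanced_accuracy,
               (rep_$sensitivity + rep_$specificity) / 2)
  expect_equal(sum(rep_$prevalence_predicted[1:3]), 1)
  expect_equal(sum(rep_$prevalence_true[1:3]), 1)
  mu <- rep_[rep_$class == "mu", ]
  expect_equal(mu$sensitivity, mean(rep_$sensitivity[1:3]))
  # perfect predictions give all-ones metrics
  perfect <- compute_metrics(diag(c(5, 7, 3)))
  expect_true(all(abs(as.matrix(perfect[, c("sensitivity", "specificity",
                                            "ppv", "npv",
                                            "balanced_accuracy")]) - 1)
                  < 1e-12))
  expect_equal(overall_accuracy(diag(c(5, 7, 3))), 1)
  expect_equal(overall_accuracy(cm), sum(diag(cm)) / sum(cm))
  expect_error(compute_metrics(matrix(0, 3, 3)), "empty")
})

test_that("zero-denominator classes are excluded from the macro mean", {
  cm <- matrix(c(5, 0, 0, 5, 0, 0, 0, 0, 0), 3, byrow = TRUE,
               dimnames = list(c("B", "T", "TB"), c("B", "T", "TB")))
  expect_warning(rep_ <- compute_metrics(cm), "zero-denominator")
  expect_true(is.nan(rep_$sensitivity[3]))  # no true TB
  expect_equal(rep_$sensitivity[4], mean(rep_$sensitivity[1:2]))
})

test_that("stratified folds have the right shape and coverage", {
  labels <- rep(c("B", "T", "TB"), c(40, 40, 20))
  f <- make_folds(labels, plan = cv_plan(seed = 2))
  expect_equal(dim(f), c(100L, 3L))
  for (r in 1:3) {
    expect_equal(as.vector(table(f[, r])), rep(20L, 5))
    # stratification: each fold has 8 B, 8 T, 4 TB
    expect_true(all(table(labels, f[, r]) ==
                    matrix(c(8, 8, 4), 3, 5)))
  }
  expect_warning(make_folds(rep(c("B", "T", "TB"), c(10, 10, 3)),
                            plan = cv_plan(seed = 1)), "best-effort")
})

test_that("grouped folds never split a source image's descendants", {
  src <- rep(sprintf("img%02d", 1:10), each = 11)  # 1 original + 10 copies
  labels <- rep(rep(c("B", "T"), 5), each = 11)
  f <- make_folds(labels, groups = src, plan = cv_plan(seed = 3))
  for (r in 1:3)
    expect_true(all(tapply(f[, r], src,
                           function(v) length(unique(v))) == 1))
})

test_that("holdout splits honour the train fraction per class", {
  labels <- rep(c("B", "T", "TB"), c(40, 40, 20))
  f <- make_folds(labels, plan = cv_plan("holdout", seed = 5))
  expect_equal(ncol(f), 1)
  expect_equal(sum(f[, 1] == 1L), 70)
  expect_equal(sum(f[labels == "TB", 1] == 1L), 14)
})

test_that("cv summaries report mean and sample SD per class and metric", {
  r1 <- suppressWarnings(compute_metrics(diag(c(4, 4, 2))))
  s <- summarize_cv(list(r1, r1, r1))
  expect_true(all(s$sd == 0))
  cm2 <- matrix(c(3, 1, 0, 0, 4, 0, 0, 0, 2), 3, byrow = TRUE)
  r2 <- compute_metrics(cm2)
  s2 <- summarize_cv(list(r1, r2))
  ba_B <- s2[s2$class == "B" & s2$metric == "balanced_accuracy", ]
  v <- c(1, r2$balanced_accuracy[1])
  expect_equal(ba_B$mean, mean(v))
  expect_equal(ba_B$sd, stats::sd(v))
  expect_equal(nrow(s2), 4 * 8)
  expect_equal(stats::sd(c(0.8, 0.9)), 0.0707, tolerance = 1e-3)
})

test_that("model comparison reduces to the textbook t-test", {
  a <- c(0.81, 0.84, 0.79, 0.86, 0.82)
  b <- c(0.72, 0.75, 0.71, 0.77, 0.74)
  ht <- compare_models(a, b, paired = FALSE)
  # hand-computed Welch statistic for these fixed numbers
  tstat <- (mean(a) - mean(b)) /
    sqrt(stats::var(a) / 5 + stats::var(b) / 5)
  expect_equal(unname(ht$statistic), tstat)
  expect_lt(ht$p.value, 0.001)
  same <- compare_models(a, a, paired = TRUE)
  expect_equal(same$p.value, 1)
  shifted <- compare_models(a + 0.1, a, paired = TRUE)
  expect_lt(shifted$p.value, 1e-6)
  expect_error(compare_models(a, b[1:3], paired = TRUE), "equal-length")
})

test_that("cross-validated evaluation is reproducible and complete", {
  q <- quick_dataset()
  x <- q$traits[, trait_names()]
  cv1 <- quick_cv("rf")
  expect_length(cv1$per_fold, 15)   # 3 repeats x 5 folds
  expect_equal(nrow(cv1$predictions), 3 * length(q$labels))
  cv2 <- suppressWarnings(
    evaluate_model(x, q$labels, "rf", plan = cv_plan(seed = 7)))
  expect_equal(cv1$pooled, cv2$pooled)
  expect_equal(cv1$predictions$max_probability,
               cv2$predictions$max_probability)
})

test_that("unsupervised evaluation never leaks labels into clustering", {
  q <- quick_dataset()
  x <- q$traits[, trait_names()]
  cv_full <- quick_cv("kmeans")
  # the full-matrix clustering is label-blind: refitting without labels
  # gives identical clusters
  fit_blind <- rsa_classifier(x, y = NULL, method = "kmeans", seed = 7)
  fit_used <- rsa_classifier(x, q$labels, method = "kmeans", seed = 7)
  expect_equal(fit_blind$fit$cluster, fit_used$fit$cluster)
  expect_s3_class(cv_full, "rsa_cv")
  # per-fold mode also runs
  cv_pf <- suppressWarnings(evaluate_model(
    x[1:60, ], q$labels[1:60], "kmeans",
    plan = cv_plan(k = 3, repeats = 1, seed = 2),
    unsupervised_mode = "per_fold"))
  expect_length(cv_pf$per_fold, 3)
})
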