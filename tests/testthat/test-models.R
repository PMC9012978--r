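test_that("min-max normalization follows the 0-1 formula", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  p <- fit_minmax(x)
  xn <- apply_minmax(x, p)
  expect_equal(unname(xn[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(xn[, "b"]), c(0, 0, 0))  # constant column convention
  # test-set extrapolation is left unclipped
  xt <- apply_minmax(cbind(a = 8, b = 5), p)
  expect_equal(unname(xt[1, "a"]), 1.5)
  expect_error(fit_minmax(cbind(a = c(1, NA))), "a")
})

test_that("cluster alignment maximizes agreement deterministically", {
  truth <- rep(c("B", "T", "TB"), each = 20)
  clusters <- rep(c(3, 1, 2), each = 20)   # pure relabelling
  al <- align_clusters(clusters, truth)
  expect_equal(al$agreement, 1)
  expect_equal(al$labels, truth)
  # everything in one cluster maps to the majority class
  truth2 <- c(rep("T", 30), rep("B", 10), rep("TB", 5))
  al2 <- align_clusters(rep(1, 45), truth2)
  expect_equal(unname(al2$mapping["1"]), "T")
  # random clusters vs balanced truth: agreement tends to 1/3
  set.seed(4)
  n <- 3000
  truth3 <- sample(rep(c("B", "T", "TB"), n / 3))
  cl3 <- sample(1:3, n, replace = TRUE)
  expect_equal(align_clusters(cl3, truth3)$agreement, 1 / 3,
               tolerance = 0.05)
})

test_that("k-means and PAM recover well-separated blobs exactly", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60, sd = 0.3), 30, 2), 2, centers[k, ], "+")))
  colnames(X) <- c("t1", "t2")
  truth <- rep(c("B", "T", "TB"), each = 30)
  for (meth in c("kmeans", "pam")) {
    fit <- rsa_classifier(X, truth, method = meth, seed = 2)
    pred <- predict(fit, X)
    expect_equal(as.character(pred$predicted_class), truth)
  }
  # brute-force nearest-centroid check for k-means
  fit <- rsa_classifier(X, truth, method = "kmeans", seed = 2,
                        normalize = FALSE)
  cen <- fit$fit$centers
  nearest <- apply(X, 1, function(r)
    which.min(colSums((t(cen) - r)^2)))
  expect_equal(unname(fit$fit$cluster), unname(nearest))
  # PAM medoids are data points
  fitp <- rsa_classifier(X, truth, method = "pam", seed = 2,
                         normalize = FALSE)
  for (i in 1:3)
    expect_true(any(apply(X, 1, function(r)
      all(r == fitp$fit$medoids[i, ]))))
})

test_that("k = 1 clustering collapses to the grand mean", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- rsa_classifier(X, method = "kmeans", seed = 1, normalize = FALSE,
                        control = list(k = 1))
  expect_equal(unname(fit$fit$centers[1, ]), unname(colMeans(X)))
  expect_error(rsa_classifier(X[1:2, ], method = "kmeans",
                              control = list(k = 5)), "k exceeds")
})

test_that("random forest separates linearly separable traits", {
  set.seed(3)
  n <- 60
  X <- cbind(t1 = c(rnorm(n, 0), rnorm(n, 6), rnorm(n, 3)),
             t2 = c(rnorm(n, 0), rnorm(n, 6), rnorm(n, 3)))
  y <- rep(c("B", "T", "TB"), each = n)
  fit <- rsa_classifier(X, y, method = "rf", seed = 1)
  pred <- predict(fit, X)
  cm <- confusion_matrix(y, pred$predicted_class)
  mu <- compute_metrics(cm)
  expect_gte(mu$balanced_accuracy[mu$class == "mu"], 0.99)
  expect_equal(fit$fit$ntree, 500)
})

test_that("probability triples resolve to argmax with B < T < TB ties", {
  votes <- matrix(c(400, 80, 20) / 500, 1,
                  dimnames = list(NULL, c("B", "T", "TB")))
  pr <- prediction_result(votes)
  expect_equal(pr$prob_B, 0.80)
  expect_equal(as.character(pr$predicted_class), "B")
  tie <- prediction_result(matrix(rep(1 / 3, 3), 1,
                                  dimnames = list(NULL, c("B", "T", "TB"))))
  expect_equal(as.character(tie$predicted_class), "B")
  near <- prediction_result(matrix(c(0.346, 0.335, 0.319), 1,
                                   dimnames = list(NULL, c("B", "T", "TB"))))
  expect_equal(as.character(near$predicted_class), "B")
  expect_equal(near$max_probability, 0.346)
  expect_error(prediction_result(matrix(c(0.5, 0.2, 0.2), 1)), "sum to 1")
})

test_that("naive Bayes posteriors collapse to priors when classes match", {
  g <- seq(0, 1, length.out = 12)
  X <- cbind(t1 = rep(g, 4), t2 = rep(rev(g), 4))
  y <- c(rep("B", 24), rep("T", 12), rep("TB", 12))  # priors 1/2, 1/4, 1/4
  fit <- rsa_classifier(X, y, method = "nb", normalize = FALSE)
  pred <- predict(fit, cbind(t1 = 0.5, t2 = 0.5))
  expect_equal(pred$prob_B, 0.5, tolerance = 0.05)
  expect_equal(pred$prob_T, 0.25, tolerance = 0.05)
})

test_that("supervised fits demand labels and at least two classes", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(rsa_classifier(X, method = "rf"), "requires labels")
  expect_error(rsa_classifier(X, rep("B", 10), method = "nb"),
               "at least 2 classes")
  fit <- rsa_classifier(X, rep(c("B", "T"), 5), method = "rf", seed = 1)
  expect_error(predict(fit, matrix(0, 1, 1, dimnames = list(NULL, "a"))),
               "lacks traits: b")
})

test_that("identical seeds reproduce identical models and predictions", {
  q <- quick_dataset()
  x <- q$traits[, trait_names()]
  for (meth in c("rf", "mlp_modern")) {
    f1 <- rsa_classifier(x, q$labels, method = meth, seed = 11)
    f2 <- rsa_classifier(x, q$labels, method = meth, seed = 11)
    expect_equal(predict(f1, x), predict(f2, x))
  }
})

test_that("the classic MLP warns when the step cap halts training", {
  set.seed(6)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("B", "T"), 20)
  expect_warning(
    rsa_classifier(X, y, method = "mlp_classic", seed = 1,
                   control = list(stepmax = 5)),
    "stepmax")
})

test_that("both MLPs learn the quick benchmark beyond chance", {
  q <- quick_dataset()
  x <- q$traits[, trait_names()]
  for (meth in c("mlp_classic", "mlp_modern")) {
    fit <- suppressWarnings(
      rsa_classifier(x, q$labels, method = meth, seed = 4))
    pred <- predict(fit, x)
    expect_true(all(abs(pred$prob_B + pred$prob_T + pred$prob_TB - 1) <
                    1e-9))
    acc <- mean(as.character(pred$predicted_class) == q$labels)
    expect_gt(acc, 0.6)
  }
})
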