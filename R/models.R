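#' Min-max normalization parameters
#'
#' Fits the 0-1 rescaling y_nor = (y - y_min) / (y_max - y_min) per trait on
#' a training matrix. Applied test values may fall outside \[0, 1\] (they
#' are deliberately not clipped); constant traits map to 0 by convention.
#'
#' @param x Numeric matrix or data.frame of traits (columns).
#' @return A list of class `minmax_params` with per-column `min` and `max`.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty training matrix")
  if (any(is.na(x))) {
    bad <- colnames(x)[apply(x, 2, anyNA)]
    stop("NaN/NA in traits: ", paste(bad, collapse = ", "))
  }
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_params")
}

#' @rdname fit_minmax
#' @param params A `minmax_params` object from [fit_minmax()].
#' @export
apply_minmax <- function(x, params) {
  x <- as.matrix(x)
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map unlabeled clusters to classes by optimal assignment
#'
#' Searches all one-to-one assignments of clusters to the classes
#' B, T, TB and keeps the one maximizing total agreement with the supplied
#' reference labels; ties break deterministically on the first-enumerated
#' permutation.
#'
#' @param clusters Integer cluster ids (1..3, fewer allowed).
#' @param truth Reference class labels in `{B, T, TB}`.
#' @return `list(labels = mapped class labels, mapping = named map
#'   cluster -> class, agreement = fraction agreeing)`.
#' @export
align_clusters <- function(clusters, truth) {
  stopifnot(length(clusters) == length(truth))
  truth <- as.character(truth)
  ids <- sort(unique(clusters))
  if (length(ids) > 3) stop("more than 3 clusters")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- -1; best_map <- NULL
  for (p in perms) {
    map <- stats::setNames(CLASS_LEVELS[p][seq_along(ids)], ids)
    agree <- sum(map[as.character(clusters)] == truth)
    if (agree > best) { best <- agree; best_map <- map }
  }
  list(labels = unname(best_map[as.character(clusters)]),
       mapping = best_map, agreement = best / length(truth))
}

#' Fit a root-architecture classifier
#'
#' One interface over the six benchmarked models: unsupervised k-means
#' (Hartigan-Wong, `iter.max = 100`, 10 restarts) and PAM (Euclidean), and
#' supervised random forest (`ntree = 500`,
#' `mtry = floor(sqrt(n_traits))`), Gaussian naive Bayes (Laplace = 1,
#' inert for continuous predictors), and two 15-10-5 multilayer
#' perceptrons — `mlp_classic` (logistic activations, cross-entropy,
#' resilient backpropagation with weight backtracking, `stepmax = 1e5`) and
#' `mlp_modern` (ReLU hidden layers, softmax output, categorical
#' cross-entropy, Adam). Traits are min-max normalized to \[0, 1\] inside
#' the fit (parameters stored and re-applied at prediction).
#'
#' For the unsupervised methods `y` is never shown to the clustering
#' itself; when supplied it is used only afterwards, to map clusters to
#' classes via [align_clusters()].
#'
#' @param x Trait matrix or data.frame (rows = roots).
#' @param y Class labels in `{B, T, TB}`; required for supervised methods.
#' @param method One of `"kmeans"`, `"pam"`, `"rf"`, `"nb"`,
#'   `"mlp_classic"`, `"mlp_modern"`.
#' @param seed Integer seed for the stochastic fitters.
#' @param normalize Min-max normalize traits (default TRUE).
#' @param control Named list of hyperparameter overrides (e.g. `ntree`,
#'   `stepmax`, `epochs`, `k`).
#' @return An object of class `rsa_classifier`.
#' @export
rsa_classifier <- function(x, y = NULL,
                           method = c("rf", "nb", "mlp_classic",
                                      "mlp_modern", "kmeans", "pam"),
                           seed = 1L, normalize = TRUE, control = list()) {
  method <- match.arg(method)
  x <- as.matrix(x)
  supervised <- method %in% c("rf", "nb", "mlp_classic", "mlp_modern")
  if (supervised) {
    if (is.null(y)) stop("supervised method '", method, "' requires labels")
    y <- factor(as.character(y), levels = CLASS_LEVELS)
    if (any(is.na(y))) stop("labels must be in {B, T, TB}")
    if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes in y")
  }
  if (!is.null(y) && length(y) != nrow(x)) stop("x/y length mismatch")
  norm <- if (normalize) fit_minmax(x) else NULL
  xn <- if (normalize) apply_minmax(x, norm) else x
  ctl <- control
  k <- ctl$k %||% 3L
  if (!supervised && k > nrow(xn)) stop("k exceeds number of points")

  fit <- switch(method,
    rf = with_seed(seed, randomForest::randomForest(
      x = xn, y = droplevels(y), ntree = ctl$ntree %||% 500L,
      mtry = ctl$mtry %||% floor(sqrt(ncol(xn))))),
    nb = e1071::naiveBayes(x = as.data.frame(xn), y = droplevels(y),
                           laplace = ctl$laplace %||% 1),
    mlp_classic = {
      Y <- stats::model.matrix(~ 0 + y)
      train_mlp_classic_core(xn, Y, hidden = ctl$hidden %||% c(15, 10, 5),
                             stepmax = ctl$stepmax %||% 1e5,
                             threshold = ctl$threshold %||% 0.01,
                             seed = seed)
    },
    mlp_modern = {
      Y <- stats::model.matrix(~ 0 + y)
      train_mlp_modern_core(xn, Y, hidden = ctl$hidden %||% c(15, 10, 5),
                            epochs = ctl$epochs %||% 200,
                            batch_size = ctl$batch_size %||% 32,
                            lr = ctl$lr %||% 1e-3,
                            patience = ctl$patience %||% 20, seed = seed)
    },
    kmeans = with_seed(seed, stats::kmeans(
      xn, centers = k, iter.max = ctl$iter.max %||% 100L,
      nstart = ctl$nstart %||% 10L, algorithm = "Hartigan-Wong")),
    pam = cluster::pam(xn, k = k, metric = "euclidean"))

  mapping <- NULL
  if (!supervised && !is.null(y)) {
    cl <- if (method == "kmeans") fit$cluster else fit$clustering
    mapping <- align_clusters(cl, as.character(y))$mapping
  }
  structure(list(method = method, supervised = supervised, fit = fit,
                 norm = norm, mapping = mapping,
                 trait_names = colnames(x), seed = seed,
                 levels = CLASS_LEVELS, control = ctl),
            class = "rsa_classifier")
}

#' @export
print.rsa_classifier <- function(x, ...) {
  cat(sprintf("<rsa_classifier: %s (%s), %d traits>\n", x$method,
              if (x$supervised) "supervised" else "unsupervised",
              length(x$trait_names)))
  invisible(x)
}

#' @export
summary.rsa_classifier <- function(object, ...) {
  print(object)
  if (object$method == "rf") {
    imp <- randomForest::importance(object$fit)
    cat("Top variable importance (mean Gini decrease):\n")
    print(utils::head(imp[order(-imp[, 1]), , drop = FALSE], 10))
  }
  if (object$method == "mlp_classic")
    cat(sprintf("training steps: %d (converged: %s)\n",
                object$fit$steps, object$fit$converged))
  if (!object$supervised && !is.null(object$mapping)) {
    cat("cluster -> class mapping:\n"); print(object$mapping)
  }
  invisible(object)
}

cluster_centers <- function(object) {
  if (object$method == "kmeans") object$fit$centers
  else object$fit$medoids
}

#' Predict class probabilities, labels and confidence for new roots
#'
#' Probabilities always sum to 1; the predicted class is the probability
#' argmax with deterministic tie-break in the order B < T < TB. Random
#' forest probabilities are tree-vote fractions; naive Bayes the posterior;
#' the MLPs their (normalized) output activations; for the clustering
#' methods the assignment to the nearest centre/medoid is reported as a
#' one-hot probability triple (clusters carry no calibrated probability).
#'
#' @param object An [rsa_classifier()].
#' @param newdata Trait matrix/data.frame with the training trait columns.
#' @param ... Unused.
#' @return `data.frame(prob_B, prob_T, prob_TB, predicted_class,
#'   max_probability)`.
#' @export
predict.rsa_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$trait_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks traits: ", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, object$trait_names, drop = FALSE])
  xn <- if (!is.null(object$norm)) apply_minmax(x, object$norm) else x
  P <- switch(object$method,
    rf = stats::predict(object$fit, xn, type = "prob"),
    nb = stats::predict(object$fit, as.data.frame(xn), type = "raw",
                        eps = 1e-9),
    mlp_classic = predict_mlp(object$fit, xn, "classic"),
    mlp_modern = predict_mlp(object$fit, xn, "modern"),
    {
      cen <- cluster_centers(object)
      d <- outer(seq_len(nrow(xn)), seq_len(nrow(cen)),
                 function(i, j) rowSums((xn[i, , drop = FALSE] -
                                         cen[j, , drop = FALSE])^2))
      cl <- max.col(-d, ties.method = "first")
      map <- object$mapping %||%
        stats::setNames(CLASS_LEVELS[seq_len(nrow(cen))],
                        seq_len(nrow(cen)))
      oh <- matrix(0, nrow(xn), 3, dimnames = list(NULL, CLASS_LEVELS))
      oh[cbind(seq_len(nrow(xn)), match(map[as.character(cl)],
                                        CLASS_LEVELS))] <- 1
      oh
    })
  P <- as.matrix(P)
  cn <- colnames(P)
  cn <- if (is.null(cn)) CLASS_LEVELS[seq_len(ncol(P))] else sub("^y", "", cn)
  colnames(P) <- cn
  # expand to the full class set (a class absent from training gets 0)
  full <- matrix(0, nrow(P), 3, dimnames = list(NULL, CLASS_LEVELS))
  keep <- intersect(cn, CLASS_LEVELS)
  full[, keep] <- P[, keep, drop = FALSE]
  P <- full
  P[!is.finite(P)] <- 1 / 3
  P <- P / rowSums(P)
  prediction_result(P)
}

#' Assemble a prediction-result table from a probability matrix
#'
#' @param P Matrix with columns B, T, TB of nonnegative rows summing to 1.
#' @return `data.frame(prob_B, prob_T, prob_TB, predicted_class,
#'   max_probability)`; argmax ties break in the order B < T < TB.
#' @export
prediction_result <- function(P) {
  P <- as.matrix(P)
  colnames(P) <- colnames(P) %||% CLASS_LEVELS
  P <- P[, CLASS_LEVELS, drop = FALSE]
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("probability rows must be nonnegative and sum to 1")
  idx <- max.col(P, ties.method = "first")
  data.frame(prob_B = P[, "B"], prob_T = P[, "T"], prob_TB = P[, "TB"],
             predicted_class = factor(CLASS_LEVELS[idx],
                                      levels = CLASS_LEVELS),
             max_probability = P[cbind(seq_len(nrow(P)), idx)])
}
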