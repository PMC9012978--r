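#' Confusion matrix over the three root-architecture classes
#'
#' @param truth,predicted Class labels in `{B, T, TB}`.
#' @return 3x3 integer matrix indexed (true class, predicted class), class
#'   `rsa_confusion`.
#' @export
confusion_matrix <- function(truth, predicted) {
  t_ <- factor(as.character(truth), levels = CLASS_LEVELS)
  p_ <- factor(as.character(predicted), levels = CLASS_LEVELS)
  if (any(is.na(t_)) || any(is.na(p_))) stop("labels must be in {B, T, TB}")
  m <- table(truth = t_, predicted = p_)
  structure(unclass(m), class = c("rsa_confusion", "matrix"))
}

#' Seven per-class quality metrics from a confusion matrix
#'
#' One-vs-rest collapse per class gives TP/FP/TN/FN, from which
#' sensitivity, specificity, positive and negative predictive value,
#' precision (identical to PPV by definition), predicted and true
#' prevalence, and balanced accuracy = (sensitivity + specificity) / 2 are
#' computed. "Prevalence" in the reported tables is the PREDICTED class
#' proportion; the true proportion is carried alongside under an
#' unambiguous name. The macro mean row `mu` is the unweighted mean over
#' the three classes; classes with a zero denominator yield `NaN` and are
#' excluded from `mu` with a warning.
#'
#' @param cm A 3x3 confusion matrix (`rsa_confusion` or plain matrix,
#'   true classes in rows).
#' @return `data.frame` with rows B, T, TB, mu and the metric columns.
#' @export
compute_metrics <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  total <- sum(cm)
  per <- lapply(seq_len(3), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    data.frame(class = CLASS_LEVELS[k],
               sensitivity = sens, specificity = spec,
               ppv = TP / (TP + FP), npv = TN / (TN + FN),
               precision = TP / (TP + FP),
               prevalence_predicted = (TP + FP) / total,
               prevalence_true = (TP + FN) / total,
               balanced_accuracy = (sens + spec) / 2)
  })
  out <- do.call(rbind, per)
  vals <- out[, -1]
  if (any(is.na(vals)))
    warning("zero-denominator class excluded from macro mean")
  mu <- colMeans(vals, na.rm = TRUE)
  out <- rbind(out, cbind(data.frame(class = "mu"), as.data.frame(t(mu))))
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Overall accuracy (correct calls over total)
#'
#' The plain proportion of correctly classified roots; distinct from the
#' per-class balanced accuracy reported in [compute_metrics()].
#'
#' @param cm A confusion matrix.
#' @return Scalar in \[0, 1\].
#' @export
overall_accuracy <- function(cm) sum(diag(unclass(cm))) / sum(cm)

#' Cross-validation plan
#'
#' @param scheme `"repeated_kfold"` (default: 3x repeated stratified 5-fold)
#'   or `"holdout"` (70/30 split).
#' @param k,repeats Folds and repeats for `repeated_kfold`.
#' @param train_fraction Training fraction for `holdout`.
#' @param stratified Stratify folds by class (default TRUE).
#' @param grouped_by_source Keep all augmented descendants of one source
#'   image in the same fold as the source (default TRUE; set FALSE for the
#'   ungrouped literal protocol).
#' @param seed Integer seed.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("repeated_kfold", "holdout"), k = 5L,
                    repeats = 3L, train_fraction = 0.7, stratified = TRUE,
                    grouped_by_source = TRUE, seed = 1L) {
  structure(list(scheme = match.arg(scheme), k = as.integer(k),
                 repeats = as.integer(repeats),
                 train_fraction = train_fraction, stratified = stratified,
                 grouped_by_source = grouped_by_source,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Build (stratified, optionally grouped) fold assignments
#'
#' @param labels Class labels.
#' @param groups Optional source-image ids; with
#'   `plan$grouped_by_source = TRUE` no group straddles folds.
#' @param plan A [cv_plan()].
#' @return Integer matrix `n x repeats` of fold ids in `1..k` (one column
#'   per repeat; `holdout` returns one column with 1 = train, 2 = test).
#' @export
make_folds <- function(labels, groups = NULL, plan = cv_plan()) {
  n <- length(labels)
  labels <- as.character(labels)
  if (is.null(groups) || !plan$grouped_by_source) groups <- seq_len(n)
  gid <- as.character(groups)
  ug <- unique(gid)
  glab <- labels[match(ug, gid)]
  if (plan$scheme == "holdout") {
    reps <- 1L
    assign_one <- function(rseed) {
      f <- integer(length(ug))
      with_seed(rseed, for (cl in unique(glab)) {
        idx <- which(glab == cl)
        ntr <- round(length(idx) * plan$train_fraction)
        tr <- sample(idx, ntr)
        f[idx] <- 2L
        f[tr] <- 1L
      })
      f
    }
  } else {
    if (n < plan$k) stop("fewer samples than folds")
    reps <- plan$repeats
    assign_one <- function(rseed) {
      f <- integer(length(ug))
      with_seed(rseed, {
        strata <- if (plan$stratified) unique(glab) else "all"
        for (cl in strata) {
          idx <- if (plan$stratified) which(glab == cl) else seq_along(ug)
          if (plan$stratified && length(idx) < plan$k)
            warning("class ", cl, " has fewer members than folds; ",
                    "best-effort stratification")
          f[idx] <- sample(rep_len(seq_len(plan$k), length(idx)))
        }
      })
      f
    }
  }
  out <- vapply(seq_len(reps), function(r) {
    gf <- assign_one(plan$seed + r - 1L)
    gf[match(gid, ug)]
  }, integer(n))
  out
}

#' Benchmark one classifier under a cross-validation plan
#'
#' Supervised models are refit per training fold with min-max normalization
#' fit on the training portion only. For the unsupervised models the
#' default mirrors the benchmark protocol: the full normalized matrix is
#' clustered once, clusters are aligned to classes, and the fixed
#' assignment is scored inside each test fold
#' (`unsupervised_mode = "full"`); `"per_fold"` re-clusters each training
#' fold instead. A model failure in one fold marks the fold failed and the
#' run continues.
#'
#' @param x Trait matrix/data.frame.
#' @param y Class labels.
#' @param method Model name, see [rsa_classifier()].
#' @param plan A [cv_plan()].
#' @param groups Optional source-image ids for grouped folds.
#' @param unsupervised_mode `"full"` or `"per_fold"`.
#' @param control Hyperparameter overrides passed to [rsa_classifier()].
#' @return An object of class `rsa_cv`: per-fold metric reports, the pooled
#'   report over all test predictions, the per-root prediction table, and
#'   any fold failures.
#' @export
evaluate_model <- function(x, y, method, plan = cv_plan(), groups = NULL,
                           unsupervised_mode = c("full", "per_fold"),
                           control = list()) {
  unsupervised_mode <- match.arg(unsupervised_mode)
  x <- as.data.frame(x)
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  folds <- make_folds(y, groups, plan)
  supervised <- method %in% c("rf", "nb", "mlp_classic", "mlp_modern")
  full_fit <- NULL
  if (!supervised && unsupervised_mode == "full")
    full_fit <- rsa_classifier(x, y, method = method, seed = plan$seed)
  per_fold <- list(); preds <- list(); failures <- character(0)
  test_ids <- function(r, f) {
    if (plan$scheme == "holdout") which(folds[, r] == 2L)
    else which(folds[, r] == f)
  }
  nfold <- if (plan$scheme == "holdout") 1L else plan$k
  reps <- ncol(folds)
  for (r in seq_len(reps)) {
    for (f in seq_len(nfold)) {
      te <- test_ids(r, f)
      tr <- setdiff(seq_len(nrow(x)), te)
      tag <- sprintf("rep%d_fold%d", r, f)
      res <- tryCatch({
        if (supervised) {
          fit <- rsa_classifier(x[tr, , drop = FALSE], y[tr],
                                method = method,
                                seed = plan$seed + 1000L * r + f,
                                control = control)
          predict(fit, x[te, , drop = FALSE])
        } else if (unsupervised_mode == "full") {
          predict(full_fit, x[te, , drop = FALSE])
        } else {
          fit <- rsa_classifier(x[tr, , drop = FALSE], y[tr],
                                method = method,
                                seed = plan$seed + 1000L * r + f,
                                control = control)
          predict(fit, x[te, , drop = FALSE])
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, paste0(tag, ": ", conditionMessage(res)))
        next
      }
      cm <- confusion_matrix(y[te], res$predicted_class)
      rep_df <- compute_metrics(cm)
      rep_df$fold <- f; rep_df$repeat_ <- r
      per_fold[[tag]] <- rep_df
      res$row <- te; res$truth <- y[te]
      res$fold <- f; res$repeat_ <- r
      preds[[tag]] <- res
    }
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  pooled_cm <- confusion_matrix(predictions$truth,
                                predictions$predicted_class)
  structure(list(method = method, plan = plan, per_fold = per_fold,
                 pooled = compute_metrics(pooled_cm),
                 pooled_cm = pooled_cm,
                 predictions = predictions, failures = failures),
            class = "rsa_cv")
}

#' @export
print.rsa_cv <- function(x, ...) {
  mu <- x$pooled[x$pooled$class == "mu", ]
  cat(sprintf(
    "<rsa_cv: %s, %d scored folds%s; pooled macro balanced accuracy %.3f>\n",
    x$method, length(x$per_fold),
    if (length(x$failures)) paste0(", ", length(x$failures), " FAILED")
    else "",
    mu$balanced_accuracy))
  invisible(x)
}

#' @export
plot.rsa_cv <- function(x, metric = "balanced_accuracy", ...) {
  vals <- sapply(x$per_fold, function(r) r[r$class != "mu", metric])
  graphics::boxplot(t(vals), names = CLASS_LEVELS, ylab = metric,
                    main = x$method, ...)
  invisible(x)
}

#' Per-fold balanced accuracies of a CV run
#'
#' @param cv An `rsa_cv` object.
#' @param class Class row to extract (default the macro mean `"mu"`).
#' @return Numeric vector, one value per scored (fold, repeat).
#' @export
fold_balanced_accuracy <- function(cv, class = "mu") {
  vapply(cv$per_fold,
         function(r) r$balanced_accuracy[r$class == class], 0)
}

#' Mean and SD of each metric per class over CV folds
#'
#' @param reports List of per-fold metric reports (as in
#'   `rsa_cv$per_fold`), or an `rsa_cv` object.
#' @return `data.frame(class, metric, mean, sd)` with sample SD (n - 1).
#' @export
summarize_cv <- function(reports) {
  if (inherits(reports, "rsa_cv")) reports <- reports$per_fold
  if (length(reports) < 2) stop("need at least 2 fold reports")
  metrics <- setdiff(colnames(reports[[1]]),
                     c("class", "fold", "repeat_"))
  out <- list()
  for (cl in c(CLASS_LEVELS, "mu")) for (m in metrics) {
    v <- vapply(reports, function(r) r[[m]][r$class == cl], 0)
    out[[paste(cl, m)]] <- data.frame(class = cl, metric = m,
                                      mean = mean(v), sd = stats::sd(v))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided t-test between two models' per-fold balanced accuracies
#'
#' @param a,b `rsa_cv` objects or numeric vectors of per-fold values.
#' @param paired Pair folds (requires matched fold order and equal length).
#' @return An `htest` from [stats::t.test()].
#' @export
compare_models <- function(a, b, paired = TRUE) {
  va <- if (inherits(a, "rsa_cv")) fold_balanced_accuracy(a) else a
  vb <- if (inherits(b, "rsa_cv")) fold_balanced_accuracy(b) else b
  if (paired && length(va) != length(vb))
    stop("paired comparison requires equal-length fold vectors")
  if (paired && stats::sd(va - vb) == 0) {
    # degenerate paired case: identical (or constant-difference) vectors
    return(structure(list(statistic = c(t = if (all(va == vb)) 0 else Inf),
                          p.value = if (all(va == vb)) 1 else 0,
                          method = "Paired t-test (degenerate)",
                          estimate = mean(va - vb)),
                     class = "htest"))
  }
  stats::t.test(va, vb, paired = paired)
}
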