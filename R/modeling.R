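# PCA feature extraction, the classifier bank, stratified k-fold
# cross-validation and precision/recall/F1/accuracy reporting.
# The positive class is "infested" throughout.

#' Fit principal components on training spectra
#'
#' Mean-centered covariance eigendecomposition (via `stats::prcomp`). Either
#' a fixed component count `ncomp` or a cumulative explained-variance target
#' `var_target` selects K; with a target, K is the smallest count whose
#' cumulative ratio reaches it. Loadings follow the sign convention that the
#' largest-magnitude entry of each column is positive, making results
#' reproducible across linear-algebra backends.
#'
#' @param spectra numeric `N x B` matrix, `N > 1`.
#' @param ncomp fixed number of components (default 3; roughly 98%+ of the
#'   variance of NIR apple spectra is carried by the first three).
#' @param var_target cumulative explained-variance target in `(0, 1]`;
#'   overrides `ncomp` when given.
#' @return object of class `pca_model`: `mean` (length B), `loadings`
#'   (`B x K`, orthonormal), `explained_variance_ratio` (length K),
#'   `eigenvalues` (length K).
#' @export
fit_pca <- function(spectra, ncomp = 3, var_target = NULL) {
  X <- as.matrix(spectra)
  N <- nrow(X); B <- ncol(X)
  cs_assert(N > 1, "PCA needs more than one observation")
  kmax <- min(N - 1L, B)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  if (!is.null(var_target)) {
    cs_assert(var_target > 0 && var_target <= 1,
              "`var_target` must be in (0, 1]")
    K <- which(cumsum(ratio) >= var_target - 1e-12)[1L]
    if (is.na(K)) K <- length(ratio)
  } else {
    cs_assert(is_count(ncomp), "`ncomp` must be a positive integer")
    if (ncomp > kmax) {
      cs_stop(sprintf("ncomp (%d) exceeds min(N-1, B) = %d", ncomp, kmax),
              "calyxscan_parameter_error")
    }
    K <- as.integer(ncomp)
  }
  K <- min(K, kmax)
  L <- pc$rotation[, seq_len(K), drop = FALSE]
  # Sign convention: largest-magnitude loading entry positive.
  for (j in seq_len(K)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(mean = pc$center, loadings = L,
                 explained_variance_ratio = ratio[seq_len(K)],
                 eigenvalues = ev[seq_len(K)]),
            class = "pca_model")
}

#' Project spectra onto fitted principal components
#'
#' @param model a [fit_pca()] model.
#' @param spectra numeric `N x B` matrix with B matching the model.
#' @return `N x K` score matrix.
#' @export
transform_pca <- function(model, spectra) {
  X <- as.matrix(spectra)
  cs_assert(ncol(X) == length(model$mean),
            "band count does not match the PCA model",
            "calyxscan_alignment_error")
  sweep(X, 2L, model$mean) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d bands -> %d components (%.2f%% variance)\n",
              length(x$mean), ncol(x$loadings),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

.classifier_tags <- c("lda", "knn", "svm", "rf", "gtb", "plsda", "adaboost")

.default_hyperparams <- function(tag) {
  switch(tag,
    lda = list(),
    knn = list(k = 5),
    svm = list(kernel = "radial", cost = 1),
    rf = list(ntree = 500),
    gtb = list(nrounds = 500, max_depth = 3, eta = 0.1),
    plsda = list(ncomp = 10),
    adaboost = list(nstumps = 100),
    cs_stop(sprintf("unknown classifier tag '%s' (supported: %s)", tag,
                    paste(.classifier_tags, collapse = ", ")),
            "calyxscan_parameter_error")
  )
}

#' Train one classifier from the bank
#'
#' Supported tags: `lda`, `knn`, `svm` (RBF), `rf` (random forest), `gtb`
#' (gradient tree boosting), `plsda` (PLS regression on a 0/1-coded response
#' with a 0.5 decision threshold), `adaboost` (SAMME over decision stumps).
#' Stochastic learners are seeded explicitly; the fully resolved
#' hyperparameters are stored on the returned handle.
#'
#' @param tag classifier tag.
#' @param features numeric `N x P` matrix.
#' @param labels factor/character with both classes present.
#' @param hyperparams named list overriding the defaults (kNN `k = 5`;
#'   SVM RBF `cost = 1`; RF `ntree = 500`; GTB `nrounds = 500`,
#'   `max_depth = 3`, `eta = 0.1`; PLS-DA `ncomp = 10`; AdaBoost
#'   `nstumps = 100`).
#' @param seed integer seed for stochastic learners.
#' @return an object of class `calyx_classifier`.
#' @export
train_classifier <- function(tag, features, labels, hyperparams = list(),
                             seed = 1) {
  tag <- match.arg(tag, .classifier_tags)
  X <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("healthy", "infested"))
  cs_assert(!anyNA(y), "labels must be healthy/infested",
            "calyxscan_value_error")
  if (nlevels(droplevels(y)) < 2L) {
    cs_stop("both classes must be present in the training labels",
            "calyxscan_degenerate_label_error")
  }
  hp <- utils::modifyList(.default_hyperparams(tag), hyperparams)
  fit <- switch(tag,
    lda = MASS::lda(X, grouping = y),
    knn = list(X = X, y = y, k = hp$k),  # lazy learner
    svm = e1071::svm(X, y, kernel = hp$kernel, cost = hp$cost,
                     probability = FALSE),
    rf = {
      set.seed(seed)
      randomForest::randomForest(X, y, ntree = hp$ntree)
    },
    gtb = xgboost::xgboost(
      X, y, nrounds = hp$nrounds, max_depth = hp$max_depth,
      learning_rate = hp$eta, nthreads = 1, verbosity = 0,
      seed = as.integer(seed)),
    plsda = fit_plsda(X, y, ncomp = hp$ncomp),
    adaboost = {
      set.seed(seed)
      fit_adaboost_stumps(X, y, nstumps = hp$nstumps)
    }
  )
  structure(list(tag = tag, fit = fit, hyperparams = hp, seed = seed,
                 n_features = ncol(X)),
            class = "calyx_classifier")
}

#' Predict class labels from a fitted classifier
#'
#' @param object a `calyx_classifier`.
#' @param newdata numeric matrix with the training feature count.
#' @param ... unused.
#' @return factor of predicted labels (`healthy` / `infested`).
#' @export
predict.calyx_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  cs_assert(ncol(X) == object$n_features,
            "feature count does not match the fitted model",
            "calyxscan_alignment_error")
  lv <- c("healthy", "infested")
  out <- switch(object$tag,
    lda = as.character(stats::predict(object$fit, X)$class),
    knn = as.character(class::knn(object$fit$X, X, object$fit$y,
                                  k = object$fit$k)),
    svm = as.character(stats::predict(object$fit, X)),
    rf = as.character(stats::predict(object$fit, X)),
    gtb = {
      # predict() on a factor-trained booster returns P(second level),
      # i.e. P(infested) with the package's level order.
      ifelse(stats::predict(object$fit, X) > 0.5, "infested", "healthy")
    },
    plsda = predict_plsda(object$fit, X),
    adaboost = predict_adaboost_stumps(object$fit, X)
  )
  factor(out, levels = lv)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 R P / (R + P)`; defined as 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class precision/recall/F1 and total accuracy
#'
#' Builds the two-class report from truth and prediction: for each class,
#' precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2RP/(R+P); total
#' accuracy = correct/n. `infested` is the positive class of interest.
#'
#' @param truth,predicted factors/characters over `healthy` / `infested`.
#' @param classifier tag recorded in the report.
#' @param partition `"train"`, `"validation"` or a CV-fold tag.
#' @return an object of class `classification_report`: data frame `metrics`
#'   (class, precision, recall, f1), `accuracy`, `confusion` (2x2 matrix,
#'   truth in rows), `n_observations`, `classifier`, `partition`.
#' @export
classification_report <- function(truth, predicted, classifier = "",
                                  partition = "") {
  lv <- c("healthy", "infested")
  truth <- factor(as.character(truth), levels = lv)
  predicted <- factor(as.character(predicted), levels = lv)
  cs_assert(length(truth) == length(predicted),
            "truth and prediction lengths differ",
            "calyxscan_alignment_error")
  cm <- table(truth = truth, predicted = predicted)
  metrics <- do.call(rbind, lapply(lv, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(class = cl, precision = p, recall = r, f1 = f1_score(p, r))
  }))
  structure(list(metrics = metrics,
                 accuracy = sum(diag(cm)) / sum(cm),
                 confusion = unclass(cm),
                 n_observations = length(truth),
                 classifier = classifier, partition = partition),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s %s: accuracy %.4f (n = %d)\n",
              x$classifier, x$partition, x$accuracy, x$n_observations))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a fitted classifier on a labeled feature matrix
#'
#' @param model a `calyx_classifier`.
#' @param features numeric matrix.
#' @param labels true labels.
#' @param partition partition tag for the report.
#' @return a [classification_report()].
#' @export
evaluate <- function(model, features, labels, partition = "validation") {
  classification_report(labels, predict(model, features),
                        classifier = model$tag, partition = partition)
}

# Balanced stratified fold assignment: classes are laid out in order and a
# cycling 1..k fold sequence runs across them, so total fold sizes differ by
# at most one while within-class counts stay as even as possible.
stratified_folds <- function(labels, folds, seed) {
  y <- factor(labels)
  n <- length(y)
  cs_assert(n >= folds, "need at least as many observations as folds")
  for (cl in levels(droplevels(y))) {
    if (sum(y == cl) < folds) {
      cs_stop(sprintf(
        "class '%s' has fewer observations (%d) than folds (%d)",
        cl, sum(y == cl), folds), "calyxscan_parameter_error")
    }
  }
  set.seed(seed)
  assignment <- integer(n)
  cycle <- rep_len(seq_len(folds), n)
  pos <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- cycle[pos + seq_along(idx)]
    pos <- pos + length(idx)
  }
  assignment
}

#' Stratified k-fold cross-validation
#'
#' Stratified folding (both classes in every fold, fold sizes differing by
#' at most one), reporting the mean and standard deviation of fold accuracy
#' plus the per-fold reports. The fold assignment is drawn once from `seed`
#' and returned, so results are exactly reproducible.
#'
#' @param tag classifier tag (see [train_classifier()]).
#' @param features numeric `N x P` matrix.
#' @param labels class labels.
#' @param folds number of folds (default 5).
#' @param seed integer seed (folding + stochastic learners).
#' @param hyperparams passed to [train_classifier()].
#' @param fold_assignment optional precomputed integer fold vector; when
#'   supplied, `folds`/`seed` are not used for folding.
#' @return object of class `cv_result`: `mean_accuracy`, `sd_accuracy`,
#'   `fold_reports`, `fold_assignment`, `classifier`, `folds`, `seed`.
#' @export
cross_validate <- function(tag, features, labels, folds = 5, seed = 1,
                           hyperparams = list(), fold_assignment = NULL) {
  X <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("healthy", "infested"))
  if (is.null(fold_assignment)) {
    fold_assignment <- stratified_folds(y, folds, seed)
  }
  ks <- sort(unique(fold_assignment))
  reports <- lapply(ks, function(k) {
    tr <- fold_assignment != k
    m <- train_classifier(tag, X[tr, , drop = FALSE], y[tr], hyperparams,
                          seed = seed)
    evaluate(m, X[!tr, , drop = FALSE], y[!tr],
             partition = sprintf("cv-fold-%d", k))
  })
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  structure(list(mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 fold_accuracies = acc,
                 fold_reports = reports,
                 fold_assignment = fold_assignment,
                 classifier = tag, folds = length(ks), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold: accuracy %.4f +/- %.4f\n",
              x$classifier, x$folds, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}
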