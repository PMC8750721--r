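# Greedy sequential forward wavelength selection with a cross-validated
# accuracy criterion: start from the empty set, at each step try every
# unselected band appended to the current set, keep the one with the best
# stratified-CV mean accuracy. The fold assignment is frozen once from the
# seed, so the whole greedy path is deterministic and every candidate is
# judged on identical folds.

#' Sequential forward wavelength selection
#'
#' @param features numeric `N x B` matrix (bands in columns).
#' @param labels class labels (`healthy` / `infested`).
#' @param classifier criterion classifier tag; default `"gtb"` with a
#'   cheaper 100-round profile than the final model (override via
#'   `hyperparams`).
#' @param max_k number of bands to select; the accuracy-vs-k curve is
#'   returned in full so the user chooses the knee, no early stopping.
#' @param folds CV folds (default 5).
#' @param seed integer seed freezing the fold assignment.
#' @param wavelengths optional length-B wavelength vector (nm) carried into
#'   the result.
#' @param hyperparams criterion-classifier hyperparameters.
#' @param criterion `"accuracy"` (default) or `"f1"` (F1 of the infested
#'   class, averaged over folds).
#' @return object of class `sfs_result`: `selected_band_indices` (selection
#'   order), `selected_wavelengths_nm`, `accuracy_curve`, `classifier`,
#'   `cv_folds`, `seed`, `criterion`.
#' @export
sfs_select <- function(features, labels, classifier = "gtb", max_k,
                       folds = 5, seed = 1, wavelengths = NULL,
                       hyperparams = NULL, criterion = c("accuracy", "f1")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(features)
  B <- ncol(X)
  cs_assert(is_count(max_k) && max_k >= 1, "`max_k` must be >= 1")
  cs_assert(max_k <= B, "`max_k` must not exceed the band count")
  y <- factor(as.character(labels), levels = c("healthy", "infested"))
  if (is.null(hyperparams)) {
    hyperparams <- if (classifier == "gtb") list(nrounds = 100) else list()
  }
  fold_assignment <- stratified_folds(y, folds, seed)
  score_fun <- function(cols) {
    cv <- cross_validate(classifier, X[, cols, drop = FALSE], y,
                         seed = seed, hyperparams = hyperparams,
                         fold_assignment = fold_assignment)
    if (criterion == "accuracy") {
      cv$mean_accuracy
    } else {
      mean(vapply(cv$fold_reports, function(r) {
        r$metrics$f1[r$metrics$class == "infested"]
      }, numeric(1)))
    }
  }
  selected <- integer(0)
  curve <- numeric(0)
  for (t in seq_len(max_k)) {
    cand <- setdiff(seq_len(B), selected)
    scores <- vapply(cand, function(j) score_fun(c(selected, j)), numeric(1))
    best <- cand[which.max(scores)]  # ties -> lower band index (scan order)
    selected <- c(selected, best)
    curve <- c(curve, max(scores))
  }
  structure(list(
    selected_band_indices = selected,
    selected_wavelengths_nm = if (!is.null(wavelengths)) {
      wavelengths[selected]
    } else NULL,
    accuracy_curve = curve,
    classifier = classifier, cv_folds = folds, seed = seed,
    criterion = criterion, hyperparams = hyperparams
  ), class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf(
    "<sfs_result> %d bands by %s (%d-fold CV, %s): final %s %.4f\n",
    length(x$selected_band_indices), x$classifier, x$cv_folds, x$criterion,
    x$criterion, utils::tail(x$accuracy_curve, 1)))
  if (!is.null(x$selected_wavelengths_nm)) {
    cat("  wavelengths (nm):",
        paste(round(x$selected_wavelengths_nm, 1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Train/validation report for a fixed band subset
#'
#' Restricts the feature matrix to `band_subset`, splits with Kennard-Stone
#' at the standard 70/30 fraction (or uses a supplied split), trains the
#' classifier on the training part and reports validation performance.
#' Useful for comparing selected subsets of different sizes against the
#' full-spectrum model.
#'
#' @param features numeric `N x B` matrix.
#' @param labels class labels.
#' @param band_subset integer band indices (non-empty, within `1..B`).
#' @param classifier classifier tag.
#' @param split optional [kennard_stone()] `split_result` on the full data.
#' @param seed seed for stochastic learners.
#' @param hyperparams classifier hyperparameters.
#' @return a [classification_report()] for the validation partition.
#' @export
subset_report <- function(features, labels, band_subset, classifier = "gtb",
                          split = NULL, seed = 1, hyperparams = list()) {
  X <- as.matrix(features)
  cs_assert(length(band_subset) >= 1, "`band_subset` must be non-empty")
  cs_assert(all(band_subset >= 1 & band_subset <= ncol(X) &
                  band_subset == round(band_subset)),
            "`band_subset` indices must be valid band positions")
  y <- factor(as.character(labels), levels = c("healthy", "infested"))
  if (is.null(split)) split <- kennard_stone(X, 0.7)
  Xs <- X[, band_subset, drop = FALSE]
  m <- train_classifier(classifier, Xs[split$train_idx, , drop = FALSE],
                        y[split$train_idx], hyperparams, seed = seed)
  evaluate(m, Xs[split$val_idx, , drop = FALSE], y[split$val_idx],
           partition = "validation")
}

#' Write an SFS result as JSON plus a two-column CSV (order, wavelength)
#'
#' @param result an `sfs_result`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_sfs_result <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(result), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(
      order = seq_along(result$selected_band_indices),
      band_index = result$selected_band_indices,
      wavelength_nm = if (!is.null(result$selected_wavelengths_nm)) {
        result$selected_wavelengths_nm
      } else NA_real_,
      accuracy = result$accuracy_curve
    ), csv_path, row.names = FALSE)
  }
  invisible(c(json = json_path, csv = csv_path))
}
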