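# Dataset assembly and the deterministic Kennard-Stone train/validation
# split used throughout chemometrics for spectral data.

#' Concatenate pixel-spectra tables into one dataset
#'
#' Row-binds tables that share an identical wavelength axis, preserving
#' labels and provenance.
#'
#' @param tables list of [pixel_spectra_table] objects.
#' @return a single [pixel_spectra_table].
#' @export
assemble_dataset <- function(tables) {
  if (length(tables) == 0L) {
    cs_stop("no tables supplied; cannot assemble an empty dataset",
            "calyxscan_empty_dataset_error")
  }
  wl <- tables[[1L]]$wavelengths
  for (t in tables) {
    if (!identical(t$wavelengths, wl)) {
      cs_stop("tables have differing wavelength axes",
              "calyxscan_alignment_error")
    }
  }
  pixel_spectra_table(
    do.call(rbind, lapply(tables, `[[`, "spectra")),
    wl,
    unlist(lapply(tables, function(t) as.character(t$labels))),
    do.call(rbind, lapply(tables, `[[`, "provenance"))
  )
}

#' Kennard-Stone train/validation split
#'
#' The classical space-filling selection: seed the training set with the two
#' points at maximum Euclidean distance, then repeatedly add the point whose
#' minimum distance to the already-selected set is largest, until
#' `round(train_fraction * N)` points are selected. Fully deterministic;
#' distance ties break toward the lower row index.
#'
#' @param spectra numeric `N x B` matrix (finite values, `N >= 2`).
#' @param train_fraction training share in `(0, 1]`; default 0.7.
#' @return an object of class `split_result`: `train_idx` (in selection
#'   order), `val_idx` (ascending), `fraction`.
#' @export
kennard_stone <- function(spectra, train_fraction = 0.7) {
  X <- as.matrix(spectra)
  N <- nrow(X)
  cs_assert(N >= 2, "Kennard-Stone needs at least two rows")
  cs_assert(all(is.finite(X)), "spectra must be finite",
            "calyxscan_value_error")
  cs_assert(train_fraction > 0 && train_fraction <= 1,
            "`train_fraction` must be in (0, 1]")
  n_train <- round(train_fraction * N)
  n_train <- max(2L, min(N, as.integer(n_train)))

  sq <- rowSums(X^2)
  # Maximum-distance seed pair, found chunk-wise to bound memory at large N.
  best <- c(0, 1L, 2L)  # (dist2, i, j)
  chunk <- 512L
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    G <- X[s:e, , drop = FALSE] %*% t(X)
    D2 <- outer(sq[s:e], sq, `+`) - 2 * G
    D2[cbind(seq_len(e - s + 1L), s:e)] <- -Inf
    w <- arrayInd(which.max(D2), dim(D2))
    d2 <- D2[w]
    if (d2 > best[1L]) best <- c(d2, s + w[1L] - 1L, w[2L])
  }
  if (best[1L] <= 0) {
    cs_stop("all rows are identical; Kennard-Stone geometry is degenerate",
            "calyxscan_degenerate_geometry_error")
  }
  seed <- sort(as.integer(best[2:3]))  # lower index first
  selected <- seed
  in_set <- logical(N)
  in_set[seed] <- TRUE
  # Minimum squared distance from each point to the selected set,
  # updated incrementally as points are added.
  d2a <- sq + sq[seed[1L]] - 2 * drop(X %*% X[seed[1L], ])
  d2b <- sq + sq[seed[2L]] - 2 * drop(X %*% X[seed[2L], ])
  mind2 <- pmin(d2a, d2b)
  mind2[in_set] <- -Inf
  while (length(selected) < n_train) {
    nxt <- which.max(mind2)  # ties -> lowest index
    selected <- c(selected, nxt)
    in_set[nxt] <- TRUE
    dn <- sq + sq[nxt] - 2 * drop(X %*% X[nxt, ])
    mind2 <- pmin(mind2, dn)
    mind2[nxt] <- -Inf
  }
  structure(list(train_idx = selected,
                 val_idx = which(!in_set),
                 fraction = train_fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d validation (fraction %.2f)\n",
              length(x$train_idx), length(x$val_idx), x$fraction))
  invisible(x)
}

#' Write a split to a two-column CSV (index, partition)
#'
#' @param split a `split_result`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_split_csv <- function(split, path) {
  df <- rbind(
    data.frame(index = split$train_idx, partition = "train"),
    data.frame(index = split$val_idx, partition = "validation")
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
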