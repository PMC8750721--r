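# The chemometric preprocessing chain applied to pixel-spectra tables, in
# fixed order: wavelength trimming -> maximum normalization -> Savitzky-Golay
# smoothing -> mean centering. The order is part of the method contract and
# is not configurable.

#' Labeled pixel-spectra table
#'
#' N pixel spectra (rows) by B bands (columns), with two-class labels and
#' per-row provenance. The canonical flat dataset of the pipeline:
#' observations are pixels, features are bands.
#'
#' @param spectra numeric `N x B` matrix.
#' @param wavelengths length-B numeric vector (nm), strictly increasing.
#' @param labels length-N character/factor, levels `healthy` / `infested`.
#' @param provenance data frame with N rows (sample_id, cultivar,
#'   orientation, row, col).
#' @return an object of class `pixel_spectra_table`.
#' @export
pixel_spectra_table <- function(spectra, wavelengths, labels, provenance) {
  spectra <- as.matrix(spectra)
  wavelengths <- as.numeric(wavelengths)
  cs_assert(ncol(spectra) == length(wavelengths),
            "column count must equal wavelength count",
            "calyxscan_alignment_error")
  cs_assert(all(diff(wavelengths) > 0), "wavelengths must strictly increase",
            "calyxscan_value_error")
  labels <- factor(as.character(labels), levels = c("healthy", "infested"))
  cs_assert(!anyNA(labels),
            "labels must be drawn from {healthy, infested}",
            "calyxscan_value_error")
  cs_assert(length(labels) == nrow(spectra),
            "one label per spectrum required", "calyxscan_alignment_error")
  cs_assert(is.data.frame(provenance) && nrow(provenance) == nrow(spectra),
            "provenance must have one row per spectrum",
            "calyxscan_alignment_error")
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 labels = labels, provenance = provenance),
            class = "pixel_spectra_table")
}

#' @export
print.pixel_spectra_table <- function(x, ...) {
  cat(sprintf(
    "<pixel_spectra_table> %d pixels x %d bands (%.1f-%.1f nm); %s\n",
    nrow(x$spectra), ncol(x$spectra), min(x$wavelengths), max(x$wavelengths),
    paste(names(table(x$labels)), table(x$labels), sep = "=",
          collapse = ", ")))
  invisible(x)
}

#' @export
dim.pixel_spectra_table <- function(x) dim(x$spectra)

.subset_rows <- function(table, idx) {
  pixel_spectra_table(table$spectra[idx, , drop = FALSE], table$wavelengths,
                      table$labels[idx],
                      table$provenance[idx, , drop = FALSE])
}

#' Preprocessing configuration
#'
#' Defaults follow the standard chain: trim to 950--1650 nm (edge bands of
#' NIR line-scan instruments are noisy), maximum normalization, second-order
#' Savitzky-Golay smoothing with a 31-point window, and mean centering with
#' the training mean.
#'
#' @param trim_low_nm,trim_high_nm trim bounds in nm.
#' @param sg_window odd Savitzky-Golay window length (default 31).
#' @param sg_order polynomial order (default 2), must be `< sg_window`.
#' @param normalize `"max"` or `"none"`.
#' @param center `"train-mean"` or `"none"`.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(trim_low_nm = 950, trim_high_nm = 1650,
                              sg_window = 31, sg_order = 2,
                              normalize = c("max", "none"),
                              center = c("train-mean", "none")) {
  normalize <- match.arg(normalize)
  center <- match.arg(center)
  cs_assert(sg_window %% 2 == 1, "`sg_window` must be odd")
  cs_assert(sg_order < sg_window, "`sg_order` must be < `sg_window`")
  cs_assert(trim_low_nm < trim_high_nm, "`trim_low_nm` must be < `trim_high_nm`")
  structure(list(trim_low_nm = trim_low_nm, trim_high_nm = trim_high_nm,
                 sg_window = sg_window, sg_order = sg_order,
                 normalize = normalize, center = center),
            class = "preprocess_config")
}

#' Trim the wavelength axis
#'
#' Keeps bands with `low_nm <= lambda <= high_nm`, slicing spectra and
#' wavelengths consistently.
#'
#' @param table a [pixel_spectra_table].
#' @param low_nm,high_nm trim bounds (nm).
#' @return a trimmed [pixel_spectra_table].
#' @export
trim_bands <- function(table, low_nm, high_nm) {
  keep <- table$wavelengths >= low_nm & table$wavelengths <= high_nm
  if (!any(keep)) {
    cs_stop(sprintf("trim window [%.1f, %.1f] nm removes every band",
                    low_nm, high_nm), "calyxscan_parameter_error")
  }
  pixel_spectra_table(table$spectra[, keep, drop = FALSE],
                      table$wavelengths[keep], table$labels, table$provenance)
}

#' Maximum normalization
#'
#' Divides each spectrum by its own maximum so every row peaks at exactly 1.
#' Removes flat multiplicative factors such as path-length and illumination
#' gain differences between pixels.
#'
#' @param table a [pixel_spectra_table].
#' @return normalized [pixel_spectra_table].
#' @export
max_normalize <- function(table) {
  mx <- apply(table$spectra, 1L, max)
  bad <- which(!(mx > 0))
  if (length(bad)) {
    cs_stop(sprintf(
      "degenerate spectra with max <= 0 at rows: %s",
      paste(utils::head(bad, 20L), collapse = ", ")),
      "calyxscan_degenerate_spectrum_error")
  }
  pixel_spectra_table(table$spectra / mx, table$wavelengths, table$labels,
                      table$provenance)
}

#' Savitzky-Golay smoothing along the band axis
#'
#' Per-row local least-squares polynomial smoothing. Edges use the
#' polynomial-fit mode (the local polynomial is evaluated at the end points
#' rather than shrinking the window), so no bands are lost.
#'
#' @param table a [pixel_spectra_table].
#' @param window odd window length (default 31).
#' @param order polynomial order (default 2).
#' @return smoothed [pixel_spectra_table].
#' @export
savgol_smooth <- function(table, window = 31, order = 2) {
  B <- ncol(table$spectra)
  cs_assert(window %% 2 == 1, "`window` must be odd")
  cs_assert(order < window, "`order` must be < `window`")
  if (window >= B + 1) {
    cs_stop(sprintf("window (%d) must not exceed band count (%d)", window, B),
            "calyxscan_parameter_error")
  }
  if (window == 1) return(table)
  # The full Savitzky-Golay projection (interior + polynomial-fit edge rows)
  # as one B x B linear map, applied to all rows at once.
  fm <- signal::sgolay(p = order, n = window)
  half <- (window - 1L) %/% 2L
  sm <- matrix(0, B, B)
  for (i in seq_len(half)) sm[i, 1:window] <- fm[i, ]
  mid <- fm[half + 1L, ]
  for (i in (half + 1L):(B - half)) sm[i, (i - half):(i + half)] <- mid
  for (i in 1:half) {
    sm[B - half + i, (B - window + 1L):B] <- fm[half + 1L + i, ]
  }
  pixel_spectra_table(table$spectra %*% t(sm), table$wavelengths,
                      table$labels, table$provenance)
}

#' Mean centering
#'
#' Subtracts a per-band mean. With `center = "fit"` the mean is computed
#' from this table (the training set) and returned for reuse; passing a
#' stored mean applies the training statistics to validation data, avoiding
#' leakage across the split.
#'
#' @param table a [pixel_spectra_table].
#' @param center `"fit"` or a stored length-B numeric vector.
#' @return list with elements `table` (centered) and `center` (the mean used).
#' @export
mean_center <- function(table, center = "fit") {
  if (identical(center, "fit")) {
    center <- colMeans(table$spectra)
  } else {
    cs_assert(is.numeric(center) && length(center) == ncol(table$spectra),
              "stored mean length must match the band count",
              "calyxscan_alignment_error")
  }
  out <- pixel_spectra_table(sweep(table$spectra, 2L, center), table$wavelengths,
                             table$labels, table$provenance)
  list(table = out, center = center)
}

#' Run the full preprocessing chain
#'
#' Applies trim, maximum normalization, Savitzky-Golay smoothing and mean
#' centering in that fixed order. For training data use `center = "fit"`;
#' for validation data pass the stored training mean.
#'
#' @param table a [pixel_spectra_table].
#' @param config a [preprocess_config()].
#' @param center `"fit"` or a stored training mean (used only when the
#'   config requests centering).
#' @return list with `table` (preprocessed) and `center` (stored mean, or
#'   `NULL` when centering is off).
#' @export
preprocess <- function(table, config = preprocess_config(), center = "fit") {
  out <- trim_bands(table, config$trim_low_nm, config$trim_high_nm)
  if (config$normalize == "max") out <- max_normalize(out)
  out <- savgol_smooth(out, config$sg_window, config$sg_order)
  if (config$center == "train-mean") {
    cc <- mean_center(out, center)
    list(table = cc$table, center = cc$center)
  } else {
    list(table = out, center = NULL)
  }
}
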