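#' Hypercube: an image cube with a wavelength axis
#'
#' The central container of the package: a 3-axis array of non-negative raw
#' intensities or calibrated reflectances with axes (row, col, band), plus the
#' band-center wavelengths in nanometres. Rows are 0-based from the top in the
#' exported coordinate convention used throughout (`(row, col)` with row 1 at
#' the top in R's 1-based indexing); the band axis is always last.
#'
#' @param data numeric 3-d array, dimensions `(H, W, B)`.
#' @param wavelengths strictly increasing numeric vector of length `B`, in nm.
#' @param name free-text identifier.
#' @param meta named list of string metadata (cultivar, orientation, label,
#'   interleave, dtype, ...).
#'
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, name = "", meta = list()) {
  cs_assert(is.array(data) && length(dim(data)) == 3L,
            "`data` must be a 3-d array (row, col, band)")
  cs_assert(all(is.finite(data)), "hypercube values must all be finite",
            "calyxscan_value_error")
  wavelengths <- as.numeric(wavelengths)
  cs_assert(length(wavelengths) == dim(data)[3L],
            sprintf("wavelength vector length (%d) must equal band count (%d)",
                    length(wavelengths), dim(data)[3L]),
            "calyxscan_alignment_error")
  cs_assert(all(diff(wavelengths) > 0),
            "wavelengths must be strictly increasing",
            "calyxscan_value_error")
  structure(
    list(data = data, wavelengths = wavelengths, name = name, meta = meta),
    class = "hypercube"
  )
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %s: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resolve a wavelength (nm) to the nearest band index
#'
#' Returns the index of the band whose centre is nearest to `target_nm`;
#' ties go to the lower index. The target must lie within the cube's
#' wavelength range extended by half the median band spacing.
#'
#' @param cube a [hypercube].
#' @param target_nm wavelength in nm.
#' @return integer band index (1-based).
#' @export
band_index <- function(cube, target_nm) {
  wl <- cube$wavelengths
  cs_assert(is.numeric(target_nm) && length(target_nm) == 1L &&
              is.finite(target_nm), "`target_nm` must be a single wavelength")
  half_step <- if (length(wl) > 1L) stats::median(diff(wl)) / 2 else Inf
  if (target_nm < min(wl) - half_step || target_nm > max(wl) + half_step) {
    cs_stop(sprintf(
      "target %.1f nm outside wavelength range [%.1f, %.1f] nm",
      target_nm, min(wl), max(wl)), "calyxscan_range_error")
  }
  which.min(abs(wl - target_nm))
}

#' Pair of white and dark reference cubes
#'
#' Holds the white-reference and dark-current images used by [calibrate()].
#' The two references must share spatial and spectral shape with each other;
#' either full-frame references or single-row (per-column, per-band line
#' averages, the push-broom convention) are accepted.
#'
#' @param white,dark [hypercube] objects.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  cs_assert(inherits(white, "hypercube") && inherits(dark, "hypercube"),
            "white and dark must be hypercubes")
  cs_assert(identical(dim(white$data), dim(dark$data)),
            "white and dark references must share shape",
            "calyxscan_alignment_error")
  cs_assert(isTRUE(all.equal(white$wavelengths, dark$wavelengths)),
            "white and dark references must share wavelengths",
            "calyxscan_alignment_error")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

#' Collapse a full-frame reference to a per-(column, band) line average
#'
#' Push-broom instruments acquire references line-wise; averaging over the
#' row axis yields one reference spectrum per (column, band) cell, reducing
#' reference noise. The result is a 1-row hypercube broadcastable along rows.
#'
#' @param cube a reference [hypercube].
#' @return a `1 x W x B` [hypercube].
#' @export
collapse_reference <- function(cube) {
  m <- apply(cube$data, c(2L, 3L), mean)
  hypercube(array(m, dim = c(1L, dim(cube$data)[2L], dim(cube$data)[3L])),
            cube$wavelengths, name = paste0(cube$name, "_line_mean"),
            meta = cube$meta)
}
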