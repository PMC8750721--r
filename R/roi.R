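# Automatic calyx-centered ROI acquisition, plus the two comparison
# extraction modes (whole-fruit mean spectrum; manual rectangular ROI).
#
# Masks are plain logical H x W matrices with the cube's (row, col)
# convention. The acquisition chain at the segmentation wavelength
# (1084 nm by default) is: threshold -> isolate dark calyx cavity inside the
# fruit disk -> erode -> centroid of the largest component -> circular ROI.

#' Segment fruit flesh from background and calyx at one wavelength
#'
#' Thresholds the image at the band nearest `seg_nm`; bright pixels (fruit
#' flesh) become `TRUE`, the dark background and the dark calyx cavity
#' `FALSE`. The default threshold is Otsu's between-class-variance maximizer
#' computed on a 256-level histogram over the band's observed intensity
#' range; a fixed threshold can be supplied instead.
#'
#' @param cube a calibrated [hypercube].
#' @param seg_nm segmentation wavelength in nm (default 1084).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold, required when `method = "fixed"`.
#' @return logical `H x W` mask with attributes `method`, `threshold` and
#'   `seg_wavelength_nm`.
#' @export
segment_scene <- function(cube, seg_nm = 1084, method = c("otsu", "fixed"),
                          threshold = NULL) {
  method <- match.arg(method)
  b <- band_index(cube, seg_nm)
  img <- cube$data[, , b]
  rng <- range(img)
  if (method == "otsu") {
    if (diff(rng) <= 0) {
      cs_stop("constant image at the segmentation band; cannot threshold",
              "calyxscan_segmentation_error")
    }
    threshold <- EBImage::otsu(EBImage::Image((img - rng[1L]) / diff(rng)),
                               range = c(0, 1), levels = 256)
    threshold <- rng[1L] + threshold * diff(rng)
  } else {
    cs_assert(is.numeric(threshold) && length(threshold) == 1L,
              "`threshold` must be supplied for method = \"fixed\"")
  }
  mask <- img > threshold
  if (!any(mask)) {
    cs_stop("segmentation produced an empty foreground",
            "calyxscan_segmentation_error")
  }
  attr(mask, "method") <- method
  attr(mask, "threshold") <- threshold
  attr(mask, "seg_wavelength_nm") <- cube$wavelengths[b]
  mask
}

# Disk structuring element by the Euclidean rule: offset (di, dj) belongs to
# the element iff sqrt(di^2 + dj^2) <= radius.
disk_selem <- function(radius) {
  r <- as.integer(radius)
  off <- seq.int(-r, r)
  k <- outer(off, off, function(a, b) sqrt(a^2 + b^2) <= radius)
  storage.mode(k) <- "integer"
  k
}

#' Binary erosion with a disk structuring element
#'
#' Standard binary erosion: a pixel stays `TRUE` iff every pixel under the
#' disk of the given radius centred on it is `TRUE`. Pixels outside the image
#' count as background, so the mask shrinks at the image border. Radius 0 is
#' the identity.
#'
#' @param mask logical matrix.
#' @param selem_radius non-negative integer disk radius.
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, selem_radius = 2) {
  cs_assert(is.matrix(mask), "`mask` must be a matrix")
  cs_assert(is.numeric(selem_radius) && selem_radius >= 0 &&
              selem_radius == round(selem_radius),
            "`selem_radius` must be a non-negative integer")
  if (selem_radius == 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  r <- as.integer(selem_radius)
  out <- mask
  for (di in seq.int(-r, r)) {
    for (dj in seq.int(-r, r)) {
      if ((di == 0 && dj == 0) || sqrt(di^2 + dj^2) > selem_radius) next
      shifted <- matrix(FALSE, H, W)
      rs <- max(1L, 1L - di):min(H, H - di)
      cs <- max(1L, 1L - dj):min(W, W - dj)
      shifted[rs, cs] <- mask[rs + di, cs + dj]
      out <- out & shifted
    }
  }
  out
}

# 8-connected component labeling (two-pass BFS flood fill).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  next_lab <- 0L
  for (p in which(mask)) {
    if (lab[p] > 0L) next
    next_lab <- next_lab + 1L
    lab[p] <- next_lab
    frontier <- p
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      cc <- ((frontier - 1L) %/% H) + 1L
      nbr <- integer(0)
      for (k in 1:8) {
        rr <- r + dr[k]; ccc <- cc + dc[k]
        ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= W
        if (any(ok)) nbr <- c(nbr, (ccc[ok] - 1L) * H + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- next_lab
      frontier <- nbr
    }
  }
  lab
}

#' Centroid of the calyx region
#'
#' Picks the largest 8-connected component of the (eroded) calyx-candidate
#' mask and returns the arithmetic mean of its true-pixel coordinates. The
#' stem/calyx cavity is the dominant dark feature in calyx-view images, so
#' the largest blob is taken as the calyx.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return numeric `(row, col)` centroid.
#' @export
calyx_centroid <- function(mask) {
  if (!any(mask)) {
    cs_stop("no calyx candidate pixels remain", "calyxscan_no_calyx_error")
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # ties -> lowest label = first in scan order
  idx <- which(lab == keep, arr.ind = TRUE)
  c(row = mean(idx[, 1L]), col = mean(idx[, 2L]))
}

#' Circular region-of-interest mask
#'
#' Pixel `(i, j)` is inside iff the Euclidean distance from its centre to
#' `center` is at most `diameter_px / 2` (inclusive boundary), clipped at the
#' image borders.
#'
#' @param center numeric `(row, col)`, may be fractional.
#' @param diameter_px positive diameter in pixels.
#' @param shape integer `(H, W)`.
#' @return logical `H x W` mask.
#' @export
circular_roi <- function(center, diameter_px = 50, shape) {
  cs_assert(is.numeric(diameter_px) && length(diameter_px) == 1L &&
              diameter_px >= 1, "`diameter_px` must be >= 1")
  H <- shape[1L]; W <- shape[2L]
  cs_assert(center[1L] >= 1 && center[1L] <= H &&
              center[2L] >= 1 && center[2L] <= W,
            "`center` must lie inside the image", "calyxscan_range_error")
  r2 <- (diameter_px / 2)^2
  dr2 <- (seq_len(H) - center[1L])^2
  dc2 <- (seq_len(W) - center[2L])^2
  outer(dr2, dc2, `+`) <= r2
}

#' Axis-aligned rectangular ROI (manual extraction mode)
#'
#' A `height x width` rectangle centred at `center` (rows
#' `r - floor((h-1)/2)` through `r + ceiling((h-1)/2)`, likewise columns),
#' clipped at the image borders. The 10 x 10 default matches manual
#' calyx-end pixel selection, yielding 100 spectra per fully interior ROI.
#'
#' @param center integer `(row, col)`.
#' @param height,width positive integers; default 10.
#' @param shape integer `(H, W)`.
#' @return logical `H x W` mask.
#' @export
rect_roi <- function(center, height = 10, width = 10, shape) {
  cs_assert(is_count(height) && is_count(width),
            "`height` and `width` must be positive integers")
  H <- shape[1L]; W <- shape[2L]
  cs_assert(center[1L] >= 1 && center[1L] <= H &&
              center[2L] >= 1 && center[2L] <= W,
            "`center` must lie inside the image", "calyxscan_range_error")
  r0 <- round(center[1L]); c0 <- round(center[2L])
  rows <- max(1L, r0 - floor((height - 1) / 2)):min(H, r0 + ceiling((height - 1) / 2))
  cols <- max(1L, c0 - floor((width - 1) / 2)):min(W, c0 + ceiling((width - 1) / 2))
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

#' Automatic calyx-centered ROI acquisition
#'
#' The full acquisition chain on a calibrated cube: segment fruit flesh at
#' `seg_nm`, take the dark pixels enclosed by the fruit disk (hole fill minus
#' flesh) as the calyx-candidate region, erode with a disk element to obtain
#' a solid area, locate the centroid of the largest remaining component, and
#' draw a circular ROI of `diameter_px` around it.
#'
#' @param cube calibrated [hypercube].
#' @param seg_nm segmentation wavelength (default 1084 nm).
#' @param diameter_px ROI diameter in pixels (default 50).
#' @param selem_radius erosion disk radius (default 2).
#' @param method,threshold passed to [segment_scene()].
#' @return an object of class `roi_result`: list with `mask`, `centroid`,
#'   `diameter_px`, `seg_wavelength_nm`, `n_pixels`, `selem_radius`,
#'   `threshold`, `method`.
#' @export
acquire_roi <- function(cube, seg_nm = 1084, diameter_px = 50,
                        selem_radius = 2, method = c("otsu", "fixed"),
                        threshold = NULL) {
  method <- match.arg(method)
  flesh <- segment_scene(cube, seg_nm, method, threshold)
  filled <- matrix(
    as.numeric(EBImage::fillHull(EBImage::Image(
      matrix(as.numeric(flesh), nrow(flesh), ncol(flesh))))) > 0.5,
    nrow(flesh), ncol(flesh))
  calyx_cand <- filled & !flesh
  if (!any(calyx_cand)) {
    cs_stop("no dark region enclosed by the fruit disk: no calyx found",
            "calyxscan_no_calyx_error")
  }
  eroded <- erode_mask(calyx_cand, selem_radius)
  ctr <- calyx_centroid(eroded)  # errors with no-calyx if erosion emptied it
  mask <- circular_roi(ctr, diameter_px, dim(flesh))
  structure(list(
    mask = mask,
    centroid = ctr,
    diameter_px = diameter_px,
    seg_wavelength_nm = attr(flesh, "seg_wavelength_nm"),
    n_pixels = sum(mask),
    selem_radius = selem_radius,
    threshold = attr(flesh, "threshold"),
    method = method
  ), class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf(
    "<roi_result> centroid (%.2f, %.2f), diameter %d px, %d pixels, seg %.1f nm\n",
    x$centroid[1L], x$centroid[2L], x$diameter_px, x$n_pixels,
    x$seg_wavelength_nm))
  invisible(x)
}

#' Unfold masked pixels into a labeled spectra table
#'
#' One row per `TRUE` pixel in row-major scan order (row 1 left to right,
#' then row 2, ...), columns = bands. Every row carries the class label and
#' per-pixel provenance (sample id, cultivar, orientation, row, col).
#'
#' @param cube a [hypercube].
#' @param mask logical matrix matching the cube's spatial shape.
#' @param label `"healthy"` or `"infested"`.
#' @param sample_id,cultivar,orientation provenance strings.
#' @return a [pixel_spectra_table].
#' @export
extract_pixel_spectra <- function(cube, mask, label,
                                  sample_id = "", cultivar = "",
                                  orientation = "") {
  d <- dim(cube$data)
  cs_assert(is.matrix(mask) && all(dim(mask) == d[1:2]),
            "mask shape must match the cube's spatial shape",
            "calyxscan_alignment_error")
  if (!any(mask)) {
    cs_stop("mask selects no pixels; cannot build a table",
            "calyxscan_empty_mask_error")
  }
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # row-major scan
  idx <- idx[ord, , drop = FALSE]
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  spectra <- flat[(idx[, 2L] - 1L) * d[1L] + idx[, 1L], , drop = FALSE]
  pixel_spectra_table(
    spectra = spectra,
    wavelengths = cube$wavelengths,
    labels = rep(label, nrow(idx)),
    provenance = data.frame(
      sample_id = sample_id, cultivar = cultivar, orientation = orientation,
      row = idx[, 1L], col = idx[, 2L], stringsAsFactors = FALSE)
  )
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean over the `TRUE` pixels; the whole-fruit mean
#' spectrum extraction mode uses this with the fruit-disk mask.
#'
#' @param cube a [hypercube].
#' @param mask logical matrix, non-empty.
#' @return numeric vector of length B.
#' @export
mean_spectrum <- function(cube, mask) {
  d <- dim(cube$data)
  cs_assert(is.matrix(mask) && all(dim(mask) == d[1:2]),
            "mask shape must match the cube's spatial shape",
            "calyxscan_alignment_error")
  if (!any(mask)) cs_stop("empty mask", "calyxscan_empty_mask_error")
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  colMeans(flat[as.vector(mask), , drop = FALSE])
}

#' Export a binary mask as a PNG (0/255) file
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(matrix(as.numeric(mask), nrow(mask),
                                              ncol(mask)))), path)
  invisible(path)
}
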