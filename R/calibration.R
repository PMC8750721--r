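#' Reflectance calibration with white and dark references
#'
#' Converts raw sensor counts to relative reflectance,
#' \deqn{R = (R_0 - R_d) / (R_w - R_d),}
#' where \eqn{R_0} is the raw image and \eqn{R_w}, \eqn{R_d} the white and
#' dark reference images. References may be full-frame (same spatial shape as
#' the raw cube) or single-row line averages (the push-broom convention,
#' see [collapse_reference()]); single-row references are broadcast along the
#' row axis.
#'
#' Denominator cells with \eqn{|R_w - R_d| < \epsilon} would blow up; they
#' yield 0 in the output and their count is recorded in
#' `meta$n_flagged_denominator`. Negative reflectance (raw below dark) is kept
#' by default, preserving information for downstream preprocessing; `clip`
#' truncates to `[0, Inf)` and records `meta$n_clipped`.
#'
#' @param raw raw [hypercube] (counts).
#' @param refs a [reference_pair].
#' @param epsilon small positive scalar on the instrument's native count
#'   scale; default `1e-6`.
#' @param clip clip negative reflectance to zero? Default `FALSE`.
#' @return a reflectance [hypercube] with the raw cube's wavelengths.
#' @export
calibrate <- function(raw, refs, epsilon = 1e-6, clip = FALSE) {
  cs_assert(inherits(raw, "hypercube"), "`raw` must be a hypercube")
  cs_assert(inherits(refs, "reference_pair"), "`refs` must be a reference_pair")
  cs_assert(is.numeric(epsilon) && length(epsilon) == 1L && epsilon > 0,
            "`epsilon` must be a positive scalar")
  if (!isTRUE(all.equal(raw$wavelengths, refs$white$wavelengths))) {
    cs_stop("raw and reference wavelength axes differ",
            "calyxscan_alignment_error")
  }
  d <- dim(raw$data)
  dr <- dim(refs$white$data)
  if (identical(dr, d)) {
    w <- refs$white$data
    k <- refs$dark$data
  } else if (dr[1L] == 1L && dr[2L] == d[2L] && dr[3L] == d[3L]) {
    idx <- rep(1L, d[1L])
    w <- refs$white$data[idx, , , drop = FALSE]
    k <- refs$dark$data[idx, , , drop = FALSE]
  } else {
    cs_stop(sprintf(
      "reference shape (%s) neither matches raw shape (%s) nor is single-row",
      paste(dr, collapse = "x"), paste(d, collapse = "x")),
      "calyxscan_alignment_error")
  }
  denom <- w - k
  bad <- abs(denom) < epsilon
  denom[bad] <- 1
  r <- (raw$data - k) / denom
  r[bad] <- 0
  n_clipped <- 0L
  if (isTRUE(clip)) {
    n_clipped <- sum(r < 0)
    r[r < 0] <- 0
  }
  meta <- raw$meta
  meta$n_flagged_denominator <- sum(bad)
  meta$n_negative_reflectance <- sum(r < 0)
  meta$n_clipped <- n_clipped
  meta$calibrated <- "true"
  hypercube(r, raw$wavelengths, name = raw$name, meta = meta)
}
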