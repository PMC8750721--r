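# ENVI-format hypercube I/O: plain-text .hdr header + raw binary data file.
# Supported dialects: interleaves bil/bip/bsq, data types 4 (float32) and
# 12 (uint16), little endian. Values are held in memory as double regardless
# of the stored dtype.

.envi_dtype <- list(`4` = list(what = "numeric", size = 4L, signed = TRUE),
                    `12` = list(what = "integer", size = 2L, signed = FALSE))

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  cs_assert(length(lines) > 0L && grepl("^ENVI", trimws(lines[1L])),
            sprintf("'%s' is not an ENVI header (missing ENVI magic)",
                    header_path), "calyxscan_format_error")
  # Join continuation of { ... } blocks onto single logical lines.
  raw <- lines[-1L]
  merged <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in raw) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    open <- (lengths(regmatches(buf, gregexpr("\\{", buf))) >
               lengths(regmatches(buf, gregexpr("\\}", buf))))
    if (!open) {
      merged <- c(merged, buf)
      buf <- ""
    }
  }
  if (nzchar(trimws(buf))) merged <- c(merged, buf)
  kv <- list()
  for (ln in merged) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  kv
}

.header_field <- function(kv, key, header_path) {
  if (is.null(kv[[key]])) {
    cs_stop(sprintf("ENVI header '%s' is missing required field '%s'",
                    header_path, key), "calyxscan_format_error")
  }
  kv[[key]]
}

#' Read an ENVI-format hypercube
#'
#' Parses the plain-text header (`samples`, `lines`, `bands`, `data type`,
#' `interleave`, `wavelength`) and reads the companion raw binary file into a
#' `(row, col, band)` [hypercube]. The wavelength list is required: downstream
#' processing is wavelength-addressed, so band numbers alone are not accepted.
#'
#' @param header_path path to the `.hdr` file. The data file is found by
#'   replacing the extension with `.raw`/`.dat`/`.img`, or dropping it.
#' @return a [hypercube] with `meta$interleave` and `meta$dtype` recorded.
#' @export
read_envi <- function(header_path) {
  cs_assert(file.exists(header_path),
            sprintf("header file '%s' does not exist", header_path),
            "calyxscan_io_error")
  kv <- .parse_envi_header(header_path)
  W <- as.integer(.header_field(kv, "samples", header_path))
  H <- as.integer(.header_field(kv, "lines", header_path))
  B <- as.integer(.header_field(kv, "bands", header_path))
  dtype_code <- trimws(.header_field(kv, "data type", header_path))
  interleave <- tolower(trimws(.header_field(kv, "interleave", header_path)))
  wl_raw <- .header_field(kv, "wavelength", header_path)
  cs_assert(interleave %in% c("bil", "bip", "bsq"),
            sprintf("unsupported interleave '%s'", interleave),
            "calyxscan_format_error")
  spec <- .envi_dtype[[dtype_code]]
  if (is.null(spec)) {
    cs_stop(sprintf("unsupported ENVI data type code '%s' (supported: 4, 12)",
                    dtype_code), "calyxscan_format_error")
  }
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl_raw), ",")[[1L]])
  cs_assert(length(wl) == B,
            sprintf("header declares %d bands but %d wavelengths", B,
                    length(wl)), "calyxscan_format_error")

  data_path <- .envi_data_path(header_path)
  n <- as.numeric(H) * W * B
  expected_bytes <- n * spec$size
  actual_bytes <- file.info(data_path)$size
  if (!isTRUE(actual_bytes == expected_bytes)) {
    cs_stop(sprintf(
      "data file '%s' holds %s bytes but header implies %s (%dx%dx%d x %dB)",
      data_path, format(actual_bytes), format(expected_bytes), H, W, B,
      spec$size), "calyxscan_size_error")
  }
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = "little")
  v <- as.numeric(v)
  cube_data <- switch(interleave,
    bsq = aperm(array(v, dim = c(W, H, B)), c(2L, 1L, 3L)),
    bil = aperm(array(v, dim = c(W, B, H)), c(3L, 1L, 2L)),
    bip = aperm(array(v, dim = c(B, W, H)), c(3L, 2L, 1L))
  )
  hypercube(cube_data, wl,
            name = sub("\\.hdr$", "", basename(header_path)),
            meta = list(interleave = interleave, dtype = dtype_code))
}

.envi_data_path <- function(header_path) {
  stem <- sub("\\.hdr$", "", header_path)
  for (ext in c(".raw", ".dat", ".img", "")) {
    p <- paste0(stem, ext)
    if (file.exists(p) && !identical(p, header_path)) return(p)
  }
  cs_stop(sprintf("no data file found next to header '%s'", header_path),
          "calyxscan_io_error")
}

#' Write a hypercube as an ENVI header + raw binary pair
#'
#' Lossless for the chosen stored dtype: `float32` keeps values to single
#' precision, `uint16` requires integral values in `[0, 65535]`.
#'
#' @param cube a [hypercube].
#' @param header_path output `.hdr` path; data written beside it as `.raw`.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param dtype `"float32"` or `"uint16"`.
#' @return the header path, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bil", "bip", "bsq"),
                       dtype = c("float32", "uint16")) {
  interleave <- match.arg(interleave)
  dtype <- match.arg(dtype)
  cs_assert(inherits(cube, "hypercube"), "`cube` must be a hypercube")
  d <- dim(cube$data)
  H <- d[1L]; W <- d[2L]; B <- d[3L]
  perm <- switch(interleave,
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bip = aperm(cube$data, c(3L, 2L, 1L))
  )
  v <- as.vector(perm)
  data_path <- paste0(sub("\\.hdr$", "", header_path), ".raw")
  con <- tryCatch(file(data_path, "wb"),
                  error = function(e) cs_stop(
                    sprintf("cannot open '%s' for writing", data_path),
                    "calyxscan_io_error"))
  on.exit(close(con), add = TRUE)
  if (dtype == "uint16") {
    cs_assert(all(v >= 0 & v <= 65535 & v == round(v)),
              "uint16 storage requires integral values in [0, 65535]",
              "calyxscan_value_error")
    writeBin(as.integer(v), con, size = 2L, endian = "little")
    code <- 12L
  } else {
    writeBin(v, con, size = 4L, endian = "little")
    code <- 4L
  }
  hdr <- c(
    "ENVI",
    sprintf("description = {%s}", cube$name),
    sprintf("samples = %d", W),
    sprintf("lines = %d", H),
    sprintf("bands = %d", B),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", code),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, header_path)
  invisible(header_path)
}
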