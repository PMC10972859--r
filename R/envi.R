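# ENVI-style raster input/output: a plain-text .hdr file describing
# geometry, data type, interleave and the wavelength list, next to a raw
# binary data file. BIL is written; BIL, BIP and BSQ are read.

.envi_types <- list(
  `1` = list(what = "integer", size = 1, signed = FALSE),
  `2` = list(what = "integer", size = 2, signed = TRUE),
  `3` = list(what = "integer", size = 4, signed = TRUE),
  `4` = list(what = "numeric", size = 4, signed = TRUE),
  `5` = list(what = "numeric", size = 8, signed = TRUE),
  `12` = list(what = "integer", size = 2, signed = FALSE)
)

#' Write a hypercube as an ENVI-style raster
#'
#' Emits `<path>` (raw binary, band-interleaved-by-line, little endian)
#' and `<path>.hdr` (text header with samples/lines/bands, data type,
#' interleave and the wavelength list). Data type 5 (double) is the
#' default so that a write/read round trip is exact.
#'
#' @param cube A [hypercube()].
#' @param path Path of the binary data file; the header gets `.hdr`
#'   appended.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, data_type = 5) {
  stopifnot(inherits(cube, "hypercube"))
  data_type <- as.character(data_type)
  if (!data_type %in% c("4", "5")) {
    stop("write_envi() supports data types 4 (float32) and 5 (float64)",
         call. = FALSE)
  }
  spec <- .envi_types[[data_type]]
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %s", data_type),
    "interleave = bil",
    "byte order = 0",
    sprintf("wavelength units = Nanometers"),
    sprintf("wavelength = { %s }",
            paste(sprintf("%.17g", cube$wavelengths), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL order: fastest samples, then bands, then lines
  v <- as.vector(aperm(cube$data, c(2, 3, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = spec$size, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # capture key = { possibly multi-line } or key = value
  pat <- "([A-Za-z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("cannot parse ENVI header: ", hdr_path, call. = FALSE)
  starts <- as.vector(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

envi_num <- function(fields, key) {
  if (is.null(fields[[key]])) {
    stop("ENVI header is missing '", key, "'", call. = FALSE)
  }
  as.numeric(fields[[key]])
}

#' Read an ENVI-style raster into a hypercube
#'
#' Honours samples, lines, bands, data type (1, 2, 3, 4, 5, 12),
#' interleave (bil/bip/bsq), byte order and the wavelength list.
#'
#' @param path Path of the binary data file; `<path>.hdr` (or the path
#'   with its extension replaced by `.hdr`) must exist.
#' @param kind Cube kind flag to set, `"raw"` or `"reflectance"`.
#' @return A [hypercube()].
#' @export
read_envi <- function(path, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) {
    hdr_path <- sub("\\.[^.]+$", ".hdr", path)
  }
  if (!file.exists(hdr_path)) {
    stop("no ENVI header found for ", path, call. = FALSE)
  }
  fields <- parse_envi_header(hdr_path)
  W <- envi_num(fields, "samples")
  H <- envi_num(fields, "lines")
  B <- envi_num(fields, "bands")
  dtype <- as.character(envi_num(fields, "data type"))
  interleave <- tolower(trimws(if (is.null(fields[["interleave"]])) "bsq"
                               else fields[["interleave"]]))
  byte_order <- if (is.null(fields[["byte order"]])) 0
                else envi_num(fields, "byte order")
  endian <- if (byte_order == 0) "little" else "big"
  spec <- .envi_types[[dtype]]
  if (is.null(spec)) {
    stop("unsupported ENVI data type: ", dtype, call. = FALSE)
  }
  wl <- if (!is.null(fields[["wavelength"]])) {
    as.numeric(strsplit(gsub("[{}]", "", fields[["wavelength"]]),
                        ",")[[1]])
  } else {
    seq_len(B)
  }
  n <- W * H * B
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) != n) {
    stop("ENVI data file is truncated: expected ", n, " values, read ",
         length(v), call. = FALSE)
  }
  data <- switch(interleave,
    bil = aperm(array(v, c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, c(B, W, H)), c(3, 2, 1)),
    bsq = aperm(array(v, c(W, H, B)), c(2, 1, 3)),
    stop("unsupported interleave: ", interleave, call. = FALSE)
  )
  hypercube(data, wl, kind = kind)
}
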