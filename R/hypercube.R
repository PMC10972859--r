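# Hyperspectral cubes: an H x W x B array (lines x samples x bands) plus
# its wavelength axis, a kind flag (raw counts vs reflectance) and an
# optional fruit mask. ENVI-style reader/writer lives in envi.R.

#' Construct a hypercube
#'
#' @param data Numeric H x W x B array (row-major line, sample, band).
#' @param wavelengths Band centres in nm, length B.
#' @param kind `"raw"` (sensor counts) or `"reflectance"`.
#' @param mask Optional logical H x W matrix, `TRUE` = fruit pixel.
#' @return A `hypercube` object.
#' @export
hypercube <- function(data, wavelengths,
                      kind = c("raw", "reflectance"), mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3)
  validate_grid(wavelengths)
  if (dim(data)[3] != length(wavelengths)) {
    stop(sprintf("cube has %d bands but grid has %d wavelengths",
                 dim(data)[3], length(wavelengths)), call. = FALSE)
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  }
  structure(list(data = data, wavelengths = wavelengths, kind = kind,
                 mask = mask),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  if (!is.null(x$mask)) {
    cat(sprintf("  mask: %d / %d pixels\n", sum(x$mask), d[1] * d[2]))
  }
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

check_same_geometry <- function(a, b, what) {
  da <- dim(a)
  db <- dim(b)
  axes <- c("lines", "samples", "bands")
  for (i in 1:3) {
    if (da[i] != db[i]) {
      stop(sprintf("%s geometry mismatch on %s axis: %d vs %d",
                   what, axes[i], da[i], db[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Reflectance correction against dark and white references
#'
#' Converts raw sensor counts to relative reflectance,
#' `R = (raw - dark) / (white - dark)`, per pixel and band. Pixels where
#' the white-dark dynamic range does not exceed `epsilon` in every band
#' cannot be calibrated; they are excluded from the output mask rather
#' than clipped or filled. Reflectance values are deliberately not
#' clipped to \[0, 1\].
#'
#' @param raw A `hypercube` of kind `"raw"`.
#' @param white,dark Reference frames: `hypercube`s or H x W x B arrays of
#'   matching geometry.
#' @param epsilon Minimum usable `white - dark` difference (counts).
#' @return A `hypercube` of kind `"reflectance"` with the updated mask.
#' @export
calibrate_reflectance <- function(raw, white, dark, epsilon = 1e-6) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$kind != "raw") {
    stop("calibrate_reflectance() expects a raw cube", call. = FALSE)
  }
  w <- if (inherits(white, "hypercube")) white$data else white
  d <- if (inherits(dark, "hypercube")) dark$data else dark
  check_same_geometry(raw$data, w, "white frame")
  check_same_geometry(raw$data, d, "dark frame")
  denom <- w - d
  refl <- (raw$data - d) / denom
  invalid_px <- apply(denom <= epsilon, c(1, 2), any)
  refl[is.na(refl) | !is.finite(refl)] <- NA_real_
  mask <- if (is.null(raw$mask)) !invalid_px else raw$mask & !invalid_px
  hypercube(refl, raw$wavelengths, kind = "reflectance", mask = mask)
}

#' Segment the fruit region of interest
#'
#' Thresholds a near-infrared band (fruit is bright, background dark) and
#' keeps the largest connected component.
#'
#' @param cube A reflectance `hypercube`.
#' @param threshold Reflectance threshold in (0, 1); pixels above it are
#'   candidate fruit.
#' @param band_nm Band used for thresholding, in nm (default 800 nm, where
#'   fruit/background contrast is strong).
#' @return Logical H x W mask (also attached to nothing; assign it to the
#'   cube yourself or pass it downstream). Warns and returns an all-FALSE
#'   mask if nothing exceeds the threshold.
#' @export
segment_roi <- function(cube, threshold = 0.15, band_nm = 800) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    stop("segment_roi() expects a reflectance cube", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  b <- nearest_band(band_nm, cube$wavelengths)
  plane <- cube$data[, , b]
  cand <- !is.na(plane) & plane > threshold
  if (!is.null(cube$mask)) cand <- cand & cube$mask
  if (!any(cand)) {
    warning("segment_roi(): no pixel exceeds the threshold; empty mask")
    return(cand)
  }
  labels <- EBImage::bwlabel(cand)
  counts <- tabulate(labels[labels > 0])
  cand & (labels == which.max(counts))
}

#' Mean spectrum over a mask
#'
#' @param cube A `hypercube`.
#' @param mask Logical H x W matrix; defaults to the cube's mask.
#' @return Numeric length-B vector: the per-band arithmetic mean over
#'   masked pixels.
#' @export
mean_spectrum <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask) || !any(mask)) {
    stop("mean_spectrum() needs a non-empty mask", call. = FALSE)
  }
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(flat[which(mask), , drop = FALSE])
}
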