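# Standard normal variate (SNV) scatter correction. Each spectrum is
# centred and scaled by its own mean and standard deviation, which removes
# exactly the per-sample multiplicative gain and additive offset caused by
# particle-size and surface-scatter effects.

# Population (divide-by-B) standard deviation of each row of a matrix.
row_pop_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

#' Standard normal variate transform of one spectrum
#'
#' Computes `(x - mean(x)) / sd_pop(x)` where `sd_pop` is the population
#' standard deviation (divide by the number of bands). The convention
#' matters because downstream calibration coefficients are scale
#' sensitive; this package uses the population form everywhere.
#'
#' @param x Numeric spectrum (length >= 2).
#' @return Numeric vector with mean 0 and population standard deviation 1.
#' @export
#' @examples
#' snv(c(1, 2, 3))
snv <- function(x) {
  if (!is.numeric(x) || length(x) < 2 || any(!is.finite(x))) {
    stop("snv() needs a finite numeric spectrum of length >= 2",
         call. = FALSE)
  }
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s <= .Machine$double.eps * (abs(mu) + 1)) {
    stop("constant_spectrum: SNV is undefined for a spectrum with zero ",
         "standard deviation", call. = FALSE)
  }
  (x - mu) / s
}

#' SNV-preprocess a spectra table
#'
#' Applies [snv()] row-wise to the full spectrum of every sample and tags
#' the result as `"snv-full-spectrum"`. SNV must always be applied to the
#' complete band axis *before* any wavelength subsetting: the per-sample
#' mean and standard deviation change when bands are dropped, so
#' subsetting first would put predictors on a different scale than the
#' calibration coefficients expect.
#'
#' @param spectra A spectra tibble (`sample_id` + band columns).
#' @return The SNV-transformed spectra tibble, tagged as preprocessed.
#' @export
#' @examples
#' sim <- simulate_samples(sim_config(n_per_stage = 3))
#' z <- snv_spectra(sim$spectra)
snv_spectra <- function(spectra) {
  m <- spectra_matrix(spectra)
  wl <- attr(m, "wavelengths")
  mu <- rowMeans(m)
  s <- row_pop_sd(m)
  bad <- s <= .Machine$double.eps * (abs(mu) + 1)
  if (any(bad)) {
    stop("constant_spectrum: sample(s) ",
         paste(utils::head(rownames(m)[bad], 5), collapse = ", "),
         " have zero spectral standard deviation", call. = FALSE)
  }
  out <- as_spectra_tibble((m - mu) / s, wl, spectra$sample_id)
  set_preprocessing(out, "snv-full-spectrum")
}

#' Pixel-wise SNV over a hypercube
#'
#' Applies [snv()] independently to the spectrum of every masked pixel.
#' Pixels whose spectrum is constant (zero standard deviation) cannot be
#' normalised; they are removed from the mask and counted in a message.
#' Unmasked pixels are left untouched.
#'
#' @param cube A reflectance [hypercube()].
#' @param mask Logical H x W matrix; defaults to the cube's own mask.
#' @return The cube with masked pixels SNV-transformed and the mask
#'   possibly shrunk by degenerate pixels.
#' @export
snv_cube <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    stop("snv_cube() expects a reflectance cube; calibrate it first",
         call. = FALSE)
  }
  if (is.null(mask) || !any(mask)) {
    stop("snv_cube() needs a non-empty mask", call. = FALSE)
  }
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  idx <- which(mask)
  px <- flat[idx, , drop = FALSE]
  mu <- rowMeans(px)
  s <- row_pop_sd(px)
  bad <- s <= .Machine$double.eps * (abs(mu) + 1)
  if (any(bad)) {
    message(sum(bad), " pixel(s) with constant spectra removed from mask")
    mask[idx[bad]] <- FALSE
    idx <- idx[!bad]
    px <- px[!bad, , drop = FALSE]
    mu <- mu[!bad]
    s <- s[!bad]
  }
  flat[idx, ] <- (px - mu) / s
  cube$data <- array(flat, d)
  cube$mask <- mask
  cube$preprocessing <- "snv-full-spectrum"
  cube
}
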