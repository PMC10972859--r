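# Small shared helpers: half-up rounding for report rendering, wavelength
# formatting, and conversions between spectra tibbles and matrices.

#' Round half away from zero
#'
#' `base::round()` rounds half to even; chemometrics reports conventionally
#' round half up, and the published tables follow that convention, so report
#' rendering uses this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.8991, 2)  # 2.90
#' round_half_up(3.125, 2)   # 3.13 (base round would give 3.12)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

fmt2 <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}

# Canonical column-name encoding of a band centre in nm. Trailing zeros are
# trimmed so anchor bands print as integers ("675") and interpolated bands
# keep their decimals ("676.23").
format_wl <- function(wl) {
  out <- formatC(wl, format = "f", digits = 2)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

is_spectra_tbl <- function(x) {
  is.data.frame(x) && "sample_id" %in% names(x)
}

#' Convert a spectra table to a numeric matrix
#'
#' Spectra tables are tibbles with a `sample_id` column followed by one
#' column per band, named by the band centre in nm. This helper extracts
#' the numeric matrix and its wavelength axis.
#'
#' @param spectra A spectra tibble.
#' @return A matrix with `sample_id` rownames and a `"wavelengths"`
#'   attribute.
#' @export
spectra_matrix <- function(spectra) {
  stopifnot(is_spectra_tbl(spectra))
  band_cols <- setdiff(names(spectra), "sample_id")
  wl <- suppressWarnings(as.numeric(band_cols))
  if (anyNA(wl)) {
    stop("spectra table has non-numeric band column names: ",
         paste(utils::head(band_cols[is.na(wl)], 3), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(spectra[band_cols])
  rownames(m) <- spectra$sample_id
  attr(m, "wavelengths") <- wl
  m
}

#' Build a spectra tibble from a matrix
#'
#' @param m Samples-by-bands numeric matrix.
#' @param wavelengths Band centres in nm (one per column).
#' @param sample_id Sample identifiers; defaults to `m`'s rownames.
#' @return A spectra tibble (`sample_id` + one column per band).
#' @export
as_spectra_tibble <- function(m, wavelengths, sample_id = rownames(m)) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == length(wavelengths))
  if (is.null(sample_id)) sample_id <- sprintf("S%03d", seq_len(nrow(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- format_wl(wavelengths)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
}

# Mark a spectra table with its preprocessing state; predict() refuses
# tables whose state does not match the model's tag.
set_preprocessing <- function(spectra, tag) {
  attr(spectra, "preprocessing") <- tag
  spectra
}

preprocessing_tag <- function(spectra) {
  tag <- attr(spectra, "preprocessing", exact = TRUE)
  if (is.null(tag)) "raw" else tag
}

#' Declare a spectra table as already preprocessed
#'
#' Escape hatch for predictor tables whose values are already on a model's
#' preprocessing scale (for example, crafted test vectors). Normal use is
#' [snv_spectra()], which tags its output automatically.
#'
#' @param spectra A spectra tibble.
#' @param tag Preprocessing tag, default `"snv-full-spectrum"`.
#' @return The tagged tibble.
#' @export
as_preprocessed <- function(spectra, tag = "snv-full-spectrum") {
  set_preprocessing(spectra, tag)
}

# Deterministic fold assignment used by every cross-validated routine:
# samples are dealt to folds in row order, round-robin.
cv_folds <- function(n, k) {
  k <- min(k, n)
  rep_len(seq_len(k), n)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
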