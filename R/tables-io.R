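# CSV input/output for spectra and reference tables. The CSV header is
# `sample_id` followed by band centres in nm (spectra) or index names
# (reference values), so files are self-describing.

#' Read / write a spectra table as CSV
#'
#' The header row is `sample_id` followed by the band centres in nm;
#' reading restores the tibble layout the rest of the package expects.
#' Preprocessing state is not stored in the file: a freshly read table is
#' treated as raw.
#'
#' @param spectra A spectra tibble.
#' @param path File path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` the spectra tibble.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(is_spectra_tbl(spectra))
  utils::write.csv(spectra, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("spectra CSV must start with a 'sample_id' column",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  invisible(spectra_matrix(out))  # validates band columns
  out
}

#' Read / write a reference table as CSV
#'
#' Columns are `sample_id`, optionally `stage`, and the physicochemical
#' indices (`ssc`, `firmness`, `lstar`, `astar`, `bstar`).
#'
#' @param reference A reference tibble.
#' @param path File path.
#' @return `write_reference_csv()` returns `path` invisibly;
#'   `read_reference_csv()` the reference tibble.
#' @export
write_reference_csv <- function(reference, path) {
  stopifnot(is.data.frame(reference), "sample_id" %in% names(reference))
  utils::write.csv(reference, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("reference CSV must carry a 'sample_id' column", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  if ("stage" %in% names(out)) {
    out$stage <- factor(out$stage, levels = unique(out$stage))
  }
  out
}
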