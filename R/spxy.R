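# SPXY sample-set partitioning: Kennard-Stone max-min selection on the
# joint, normalised spectral (x) and physicochemical (y) distance.

#' SPXY calibration/prediction split
#'
#' Computes pairwise distances `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`
#' with Euclidean `dx` on SNV-preprocessed spectra and Euclidean `dy` on
#' per-index autoscaled reference values (all five indices jointly, so one
#' split serves every index). Selection is Kennard-Stone max-min: the pair
#' attaining the maximum joint distance seeds the calibration set, then
#' the sample with the largest minimum distance to the selected set is
#' added until `n_cal` samples are chosen; the remainder form the
#' prediction set. Fully deterministic; ties break to the lowest original
#' sample index.
#'
#' @param spectra Spectra tibble. SNV is applied internally unless the
#'   table is already tagged `"snv-full-spectrum"`.
#' @param reference Reference tibble with the five index columns (`ssc`,
#'   `firmness`, `lstar`, `astar`, `bstar`), row-aligned with `spectra`
#'   by `sample_id`.
#' @param n_cal Calibration-set size, `2 <= n_cal < N`.
#' @return An `spxy_split`: `cal_ids`, `pred_ids`, the full selection
#'   `order`, and sizes.
#' @export
#' @examples
#' sim <- simulate_samples(sim_config(n_per_stage = 5))
#' spxy_split(sim$spectra, sim$reference, n_cal = 14)
spxy_split <- function(spectra, reference, n_cal) {
  stopifnot(is.data.frame(reference), "sample_id" %in% names(reference))
  if (!identical(spectra$sample_id, reference$sample_id)) {
    stop("spectra and reference tables must be row-aligned by sample_id",
         call. = FALSE)
  }
  n <- nrow(spectra)
  if (n_cal < 2 || n_cal >= n) {
    stop("n_cal must satisfy 2 <= n_cal < N", call. = FALSE)
  }
  X <- if (preprocessing_tag(spectra) == "snv-full-spectrum") {
    spectra_matrix(spectra)
  } else {
    spectra_matrix(snv_spectra(spectra))
  }
  idx_cols <- intersect(.kiwi_indices, names(reference))
  if (length(idx_cols) == 0) {
    stop("reference table carries none of the five index columns",
         call. = FALSE)
  }
  Ym <- as.matrix(reference[idx_cols])
  sds <- apply(Ym, 2, stats::sd)
  Y <- scale(Ym, scale = ifelse(sds > 0, sds, 1))
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(Y))
  if (max(dx) == 0 || max(dy) == 0) {
    stop("degenerate data: zero spread in spectra or reference values",
         call. = FALSE)
  }
  d <- dx / max(dx) + dy / max(dy)
  # seed pair: maximum joint distance, ties to smallest (i, j)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- as.integer(best[1, ])
  remaining <- setdiff(seq_len(n), sel)
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < n_cal) {
    cand <- remaining[min_d[remaining] == max(min_d[remaining])]
    nxt <- min(cand)
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  order_rest <- remaining
  structure(list(
    cal_ids = sort(spectra$sample_id[sel]),
    pred_ids = sort(spectra$sample_id[order_rest]),
    order = spectra$sample_id[sel],
    n_cal = length(sel),
    n_pred = length(order_rest)
  ), class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d calibration / %d prediction samples\n",
              x$n_cal, x$n_pred))
  invisible(x)
}

#' Tidy an SPXY split
#'
#' @param x An `spxy_split`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `set` (`"calibration"` /
#'   `"prediction"`).
#' @method tidy spxy_split
#' @export
tidy.spxy_split <- function(x, ...) {
  tibble::tibble(
    sample_id = c(x$cal_ids, x$pred_ids),
    set = rep(c("calibration", "prediction"), c(x$n_cal, x$n_pred))
  )
}

#' Per-set statistics of the reference indices
#'
#' Renders the standard partition-quality table: for each set and index,
#' the minimum, maximum and mean +/- sample standard deviation of the
#' reference values, formatted to 2 decimals (half-up). For a set with
#' fewer than two samples the sd is reported as `NA`.
#'
#' @param split An [spxy_split()].
#' @param reference The reference tibble the split was made from.
#' @return A tibble with columns `set`, `n`, `index`, `units`, `min`,
#'   `max`, `mean`, `sd` (numeric) and `mean_sd` (formatted string).
#' @export
summarize_split <- function(split, reference) {
  stopifnot(inherits(split, "spxy_split"))
  idx_cols <- intersect(.kiwi_indices, names(reference))
  sets <- list(calibration = split$cal_ids, prediction = split$pred_ids)
  purrr::map_dfr(names(sets), function(set_name) {
    rows <- reference[reference$sample_id %in% sets[[set_name]], ]
    purrr::map_dfr(idx_cols, function(idx) {
      v <- rows[[idx]]
      s <- if (length(v) >= 2) stats::sd(v) else NA_real_
      tibble::tibble(
        set = set_name,
        n = length(v),
        index = idx,
        units = .kiwi_index_units[[idx]],
        min = min(v),
        max = max(v),
        mean = mean(v),
        sd = s,
        mean_sd = if (is.na(s)) paste0(fmt2(mean(v)), " ± NA")
                  else paste0(fmt2(mean(v)), " ± ", fmt2(s))
      )
    })
  })
}
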