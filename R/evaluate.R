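# Model evaluation: calibration/prediction R^2 and RMSE, residual
# predictive deviation (RPD = prediction-set reference SD / RMSEP) and its
# qualitative band, plus rendering of the model x index comparison table.

metric_r2 <- function(y_act, y_hat) {
  ss_tot <- sum((y_act - mean(y_act))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: reference values have zero variance",
         call. = FALSE)
  }
  1 - sum((y_act - y_hat)^2) / ss_tot
}

metric_rmse <- function(y_act, y_hat) sqrt(mean((y_act - y_hat)^2))

#' Qualitative RPD band
#'
#' Standard interpretation bands: RPD < 1.4 below-poor, 1.4 <= RPD < 1.8
#' poor, 1.8 <= RPD < 2.0 good, RPD >= 2.0 excellent.
#'
#' @param rpd Finite positive RPD value.
#' @return One of `"below-poor"`, `"poor"`, `"good"`, `"excellent"`.
#' @export
#' @examples
#' rpd_band(1.9)
#' rpd_band(2.0)
rpd_band <- function(rpd) {
  if (!is.numeric(rpd) || length(rpd) != 1 || !is.finite(rpd) || rpd <= 0) {
    stop("rpd_band() needs a finite positive RPD", call. = FALSE)
  }
  if (rpd < 1.4) "below-poor"
  else if (rpd < 1.8) "poor"
  else if (rpd < 2.0) "good"
  else "excellent"
}

#' Evaluate a calibration model on a calibration/prediction split
#'
#' Computes R^2 and RMSE on each set (each around that set's own mean),
#' and RPD = SD / RMSEP where SD is the *sample* standard deviation of
#' the prediction-set reference values. Raw doubles are kept; rounding
#' happens only in [report_table()].
#'
#' @param model A `chemo_model`.
#' @param spectra Preprocessed spectra tibble covering all samples.
#' @param reference Reference tibble, row-aligned by `sample_id`; the
#'   response column is `model$index` unless overridden.
#' @param split An [spxy_split()].
#' @param response Response column name (defaults to the model's index).
#' @param label Model label used in report tables (defaults to family).
#' @return An `evaluation_report` object.
#' @export
evaluate_model <- function(model, spectra, reference, split,
                           response = model$index, label = NULL) {
  stopifnot(inherits(model, "chemo_model"), inherits(split, "spxy_split"))
  if (!response %in% names(reference)) {
    stop("reference table has no column '", response, "'", call. = FALSE)
  }
  pick <- function(ids) {
    i <- match(ids, spectra$sample_id)
    list(
      X = set_preprocessing(spectra[i, , drop = FALSE],
                            preprocessing_tag(spectra)),
      y = reference[[response]][match(ids, reference$sample_id)]
    )
  }
  cal <- pick(split$cal_ids)
  prd <- pick(split$pred_ids)
  if (length(prd$y) < 2) {
    stop("prediction set needs >= 2 samples for the SD in RPD",
         call. = FALSE)
  }
  y_cal_hat <- predict(model, cal$X)
  y_prd_hat <- predict(model, prd$X)
  rmsec <- metric_rmse(cal$y, y_cal_hat)
  rmsep <- metric_rmse(prd$y, y_prd_hat)
  rpd <- if (rmsep == 0) Inf else stats::sd(prd$y) / rmsep
  structure(list(
    model = if (is.null(label)) model$family else label,
    index = model$index,
    units = model$units,
    r2_cal = metric_r2(cal$y, y_cal_hat),
    rmsec = rmsec,
    r2_pred = metric_r2(prd$y, y_prd_hat),
    rmsep = rmsep,
    rpd = rpd,
    band = if (is.finite(rpd)) rpd_band(rpd) else "excellent",
    n_cal = length(cal$y),
    n_pred = length(prd$y)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s [%s]\n", x$model, x$index,
              x$units))
  cat(sprintf("  R2C %.3f  RMSEC %.3f | R2P %.3f  RMSEP %.3f | RPD %.2f (%s)\n",
              x$r2_cal, x$rmsec, x$r2_pred, x$rmsep, x$rpd, x$band))
  invisible(x)
}

#' One-row tibble view of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A one-row tibble with the raw (unrounded) metrics.
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    model = x$model, index = x$index, units = x$units,
    r2_cal = x$r2_cal, rmsec = x$rmsec,
    r2_pred = x$r2_pred, rmsep = x$rmsep,
    rpd = x$rpd, band = x$band,
    n_cal = x$n_cal, n_pred = x$n_pred
  )
}

#' Model x index comparison table
#'
#' Collects evaluation reports into the conventional comparison layout:
#' one row per model x index, columns R2C, RMSEC, R2P, RMSEP and RPD,
#' formatted to 2 decimals with half-up rounding.
#'
#' @param reports A list of `evaluation_report` objects.
#' @param formatted If `TRUE` (default) metric columns are 2-decimal
#'   strings; otherwise raw numerics.
#' @return A tibble.
#' @export
report_table <- function(reports, formatted = TRUE) {
  if (length(reports) == 0) {
    stop("report_table() needs at least one evaluation report",
         call. = FALSE)
  }
  stopifnot(all(vapply(reports, inherits, logical(1),
                       "evaluation_report")))
  raw <- purrr::map_dfr(reports, glance)
  out <- raw[, c("model", "index", "r2_cal", "rmsec", "r2_pred",
                 "rmsep", "rpd")]
  names(out) <- c("model", "index", "R2C", "RMSEC", "R2P", "RMSEP", "RPD")
  if (formatted) {
    out <- dplyr::mutate(out, dplyr::across(
      c("R2C", "RMSEC", "R2P", "RMSEP", "RPD"),
      ~ ifelse(is.finite(.x), fmt2(.x), "Inf")))
  }
  out
}
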