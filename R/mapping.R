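# Pixel-wise model application and pseudo-colour rendering. Each masked
# pixel's full-band spectrum is SNV-normalised and pushed through the
# calibration's linear form, yielding a spatial map of the predicted
# index in physical units.

#' Pixel-wise prediction map
#'
#' Applies a calibration model to every masked pixel of a reflectance
#' cube: SNV on the pixel's full 256-band spectrum first, then
#' `y = b0 + sum_j b_j X(lambda_j)`. Pixels whose spectrum is constant
#' (SNV undefined) are dropped from the mask and counted in a message.
#' Unmasked pixels carry `NA`.
#'
#' @param cube A reflectance [hypercube()].
#' @param model A `chemo_model` whose preprocessing tag is
#'   `"snv-full-spectrum"`.
#' @param mask Logical H x W matrix (defaults to the cube's mask).
#' @param tol Wavelength matching tolerance in nm.
#' @return A `prediction_map`: `values` (H x W, `NA` off-mask), `mask`,
#'   `index`, `units`, `model` label.
#' @export
predict_map <- function(cube, model, mask = cube$mask, tol = 1) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "chemo_model"))
  if (cube$kind != "reflectance") {
    stop("predict_map() expects a reflectance cube", call. = FALSE)
  }
  if (is.null(mask) || !any(mask)) {
    stop("predict_map() needs a non-empty mask", call. = FALSE)
  }
  if (model$preprocessing != "snv-full-spectrum") {
    stop("predict_map() supports models with the 'snv-full-spectrum' tag",
         call. = FALSE)
  }
  bands <- vapply(model$wavelengths, nearest_band, integer(1),
                  grid = cube$wavelengths, tol = tol)
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  idx <- which(mask)
  px <- flat[idx, , drop = FALSE]
  mu <- rowMeans(px)
  s <- row_pop_sd(px)
  bad <- s <= .Machine$double.eps * (abs(mu) + 1)
  if (any(bad)) {
    message(sum(bad),
            " constant-spectrum pixel(s) dropped from the prediction mask")
    mask[idx[bad]] <- FALSE
    idx <- idx[!bad]
    px <- px[!bad, , drop = FALSE]
    mu <- mu[!bad]
    s <- s[!bad]
  }
  z <- (px - mu) / s
  pred <- drop(z[, bands, drop = FALSE] %*% model$coefficients) +
    model$intercept
  values <- matrix(NA_real_, d[1], d[2])
  values[idx] <- pred
  structure(list(
    values = values,
    mask = mask,
    index = model$index,
    units = model$units,
    model = model$family
  ), class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map> %s [%s], %d masked pixel(s)\n",
              x$index, x$units, sum(x$mask)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  value range: %.3f .. %.3f\n", rng[1], rng[2]))
  invisible(x)
}

#' Shared display range over a batch of prediction maps
#'
#' The default display policy is the 2.5th-97.5th percentile of the
#' pooled masked values of every map in a batch, so that one colour
#' scale serves all maturity stages and colours stay comparable across
#' images.
#'
#' @param maps A list of `prediction_map`s (or a single map).
#' @param probs Percentile pair defining the range.
#' @return Numeric `c(low, high)`.
#' @export
map_display_range <- function(maps, probs = c(0.025, 0.975)) {
  if (inherits(maps, "prediction_map")) maps <- list(maps)
  v <- unlist(lapply(maps, function(m) m$values[m$mask]))
  unname(stats::quantile(v, probs, na.rm = TRUE))
}

#' Render a prediction map in pseudo-colour
#'
#' Values are mapped linearly onto a colormap over the display range;
#' out-of-range values clip to the endpoints and background pixels take a
#' fixed neutral grey. Rendering is a pure function of
#' (values, range, colormap).
#'
#' @param map A `prediction_map`.
#' @param range Display range `c(low, high)`; defaults to this map's
#'   2.5-97.5 percentile range. Pass a shared range for cross-stage
#'   comparability.
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default `"viridis"`, perceptually uniform).
#' @param n_colors Number of colour steps.
#' @param background Background colour.
#' @return A `rendered_map`: `rgb` (H x W x 3 array in \[0, 1\]) plus
#'   colourbar metadata (`range`, `colormap`, `index`, `units`).
#' @export
render_pseudocolor <- function(map, range = NULL, colormap = "viridis",
                               n_colors = 256, background = "grey60") {
  stopifnot(inherits(map, "prediction_map"))
  if (is.null(range)) range <- map_display_range(map)
  if (!is.numeric(range) || length(range) != 2 || !all(is.finite(range)) ||
      range[1] >= range[2]) {
    stop("degenerate display range: need finite low < high", call. = FALSE)
  }
  pal <- grDevices::hcl.colors(n_colors, colormap)
  pal_rgb <- t(grDevices::col2rgb(pal)) / 255
  bg_rgb <- drop(grDevices::col2rgb(background)) / 255
  d <- dim(map$values)
  v <- (map$values - range[1]) / (range[2] - range[1])
  v <- pmin(pmax(v, 0), 1)
  bin <- 1L + as.integer(round(v * (n_colors - 1)))
  rgb <- array(rep(bg_rgb, each = d[1] * d[2]), c(d[1], d[2], 3))
  idx <- which(map$mask & !is.na(map$values))
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[idx] <- pal_rgb[bin[idx], ch]
    rgb[, , ch] <- plane
  }
  structure(list(
    rgb = rgb,
    range = range,
    colormap = colormap,
    n_colors = n_colors,
    background = background,
    index = map$index,
    units = map$units
  ), class = "rendered_map")
}

#' Write a rendered map to disk
#'
#' Emits `<path>.png` (8-bit RGB), `<path>_values.csv` (raw predicted
#' values, `NA` off-mask) and `<path>.json` (colourbar sidecar: range,
#' colormap, index, units). The PNG is bit-exact reproducible for fixed
#' inputs.
#'
#' @param rendered A `rendered_map`.
#' @param map The `prediction_map` it was rendered from (for the CSV).
#' @param path Output path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_map <- function(rendered, map, path) {
  stopifnot(inherits(rendered, "rendered_map"),
            inherits(map, "prediction_map"))
  png::writePNG(rendered$rgb, paste0(path, ".png"))
  utils::write.csv(map$values, paste0(path, "_values.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    index = rendered$index,
    units = rendered$units,
    range = rendered$range,
    colormap = rendered$colormap,
    background = rendered$background
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a prediction map
#'
#' @param object A `prediction_map`.
#' @param range Optional shared display range.
#' @param ... Unused.
#' @return A ggplot object (tile raster with a viridis fill).
#' @method autoplot prediction_map
#' @export
autoplot.prediction_map <- function(object, range = NULL, ...) {
  d <- dim(object$values)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$value <- as.vector(object$values)[(df$col - 1) * d[1] + df$row]
  if (is.null(range)) range <- map_display_range(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = range, oob = scales_squish,
                                  na.value = "grey60",
                                  name = paste0(object$index, " [",
                                                object$units, "]")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

# minimal squish (avoids a scales dependency): clamp to limits
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  x[x < range[1]] <- range[1]
  x[x > range[2]] <- range[2]
  x
}
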