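# Shared container for feature-wavelength selection results.

new_selection_result <- function(method, indices, wavelengths, trajectory,
                                 best, seed = NULL, extra = list()) {
  structure(c(list(
    method = method,
    indices = as.integer(indices),
    wavelengths = wavelengths,
    trajectory = trajectory,
    best = best,
    seed = seed
  ), extra), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d wavelength(s) selected\n",
              toupper(x$method), length(x$indices)))
  cat("  ", paste(round(x$wavelengths), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with `band` (grid index) and `wavelength_nm`.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(band = x$indices, wavelength_nm = x$wavelengths)
}

#' Error trajectory plot for a selection result
#'
#' For CARS, cross-validated RMSE per Monte Carlo sampling run (the
#' characteristic decrease-then-increase shape); for SPA, RMSE against
#' subset size. The chosen optimum is marked.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  tr <- object$trajectory
  if (object$method == "cars") {
    p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$run, y = .data$rmsecv)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = object$best, linetype = 2,
                          colour = "red") +
      ggplot2::labs(x = "Monte Carlo sampling run", y = "RMSECV",
                    title = "CARS error trajectory")
  } else {
    p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$size, y = .data$rmse)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_vline(xintercept = object$best, linetype = 2,
                          colour = "red") +
      ggplot2::labs(x = "subset size", y = "RMSE",
                    title = "SPA error trajectory")
  }
  p + ggplot2::theme_minimal()
}

#' Serialize a selection result to JSON
#'
#' @param x A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  obj <- list(
    method = x$method,
    indices = x$indices,
    wavelengths = x$wavelengths,
    best = x$best,
    seed = x$seed,
    trajectory = as.data.frame(x$trajectory)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
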