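# Calibration models: MLR (ordinary least squares on selected wavelengths)
# and PLSR (NIPALS, full spectrum). Both produce a `chemo_model` carrying
# an intercept and coefficients bound to named wavelengths, plus the
# preprocessing tag the predictors must satisfy.

new_chemo_model <- function(family, intercept, coefficients, wavelengths,
                            index, units, lv = NA_integer_,
                            preprocessing = "snv-full-spectrum",
                            source = "fitted", cv = NULL) {
  stopifnot(length(coefficients) == length(wavelengths))
  structure(
    list(
      family = family,
      intercept = intercept,
      coefficients = coefficients,
      wavelengths = wavelengths,
      index = index,
      units = units,
      lv = lv,
      preprocessing = preprocessing,
      source = source,
      cv = cv
    ),
    class = "chemo_model"
  )
}

#' @export
print.chemo_model <- function(x, ...) {
  cat(sprintf("<chemo_model> %s for %s [%s]\n", toupper(x$family),
              x$index, x$units))
  cat(sprintf("  %d wavelength term(s), intercept %.4g, preprocessing '%s'\n",
              length(x$coefficients), x$intercept, x$preprocessing))
  if (!is.na(x$lv)) cat(sprintf("  latent variables: %d\n", x$lv))
  invisible(x)
}

#' Fit a multiple linear regression on selected wavelengths
#'
#' Ordinary least squares of an index on the (already preprocessed)
#' spectral values at the given wavelengths, as used for the simplified
#' calibrations built on CARS- or SPA-selected bands.
#'
#' @param spectra A spectra tibble carrying the predictors (normally the
#'   output of [snv_spectra()]).
#' @param y Numeric response, one value per sample, in physical units.
#' @param wavelengths Wavelengths (nm) to use as predictors; matched to
#'   the table's band columns by nearest neighbour within `tol`.
#' @param index,units Name and units of the predicted index (metadata).
#' @param tol Wavelength matching tolerance in nm.
#' @return A `chemo_model` of family `"mlr"`.
#' @export
fit_mlr <- function(spectra, y, wavelengths, index = "index", units = "",
                    tol = 1) {
  m <- spectra_matrix(spectra)
  grid <- attr(m, "wavelengths")
  stopifnot(length(y) == nrow(m))
  bands <- vapply(wavelengths, nearest_band, integer(1), grid = grid,
                  tol = tol)
  if (anyDuplicated(bands)) {
    stop("wavelengths resolve to duplicated bands: ",
         paste(wavelengths[duplicated(bands)], collapse = ", "),
         call. = FALSE)
  }
  X <- m[, bands, drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p + 1) {
    stop(sprintf("need n > m + 1 samples to fit %d wavelength terms (n = %d)",
                 p, n), call. = FALSE)
  }
  D <- cbind(`(Intercept)` = 1, X)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    dropped <- qr_d$pivot[seq(qr_d$rank + 1, ncol(D))]
    stop("design matrix is rank deficient; collinear wavelengths: ",
         paste(colnames(D)[dropped], collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_d, y)
  new_chemo_model(
    family = "mlr",
    intercept = unname(beta[1]),
    coefficients = stats::setNames(unname(beta[-1]),
                                   format_wl(grid[bands])),
    wavelengths = grid[bands],
    index = index,
    units = units,
    preprocessing = preprocessing_tag(spectra)
  )
}

# ---- NIPALS PLSR (single response) ------------------------------------

# Fits up to ncomp components on centred data; returns the regression
# coefficient vectors (on the original X scale) for every component count
# 1..ncomp, so cross-validation over component counts needs one fit only.
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  ncomp <- max(1L, min(ncomp, n - 1L, p))
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- crossprod(E, t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, a] <- w
    P[, a] <- p_
    q[a] <- q_
    used <- a
  }
  if (used == 0L) stop("PLSR: response has no covariance with predictors",
                       call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  # R = W (P'W)^-1 maps X (centred) to scores; coefficients per ncomp
  R <- W %*% solve(crossprod(P, W))
  B <- vapply(seq_len(used), function(a) {
    drop(R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  }, numeric(p))
  B <- matrix(B, nrow = p)
  intercepts <- y_mean - drop(crossprod(x_mean, B))
  list(coef = B, intercept = intercepts, ncomp = used,
       x_mean = x_mean, y_mean = y_mean)
}

# k-fold cross-validated RMSE for each component count 1..max_lv.
plsr_cv_rmse <- function(X, y, max_lv, n_folds) {
  n <- nrow(X)
  folds <- cv_folds(n, n_folds)
  k <- max(folds)
  max_use <- max(1L, min(max_lv, ncol(X), n - ceiling(n / k) - 1L))
  press <- matrix(NA_real_, n, max_use)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- nipals_pls(X[!hold, , drop = FALSE], y[!hold], max_use)
    pred <- sweep(X[hold, , drop = FALSE] %*% fit$coef, 2, fit$intercept,
                  `+`)
    press[hold, seq_len(fit$ncomp)] <- (pred[, seq_len(fit$ncomp)] - y[hold])^2
  }
  rmse <- sqrt(colMeans(press))
  rmse[is.na(rmse)] <- Inf
  rmse
}

#' Fit a full-spectrum PLSR calibration
#'
#' Partial least squares regression (single-response NIPALS with
#' y-deflation) of an index on the full preprocessed spectrum. The latent
#' variable count is chosen as the argmin of k-fold cross-validated RMSE
#' over `1..max_lv`; the final model is refit on all samples at that
#' count.
#'
#' @inheritParams fit_mlr
#' @param max_lv Maximum number of latent variables considered
#'   (capped at the design rank).
#' @param n_folds Folds for the RMSECV-based latent-variable choice
#'   (deterministic round-robin assignment in row order).
#' @return A `chemo_model` of family `"plsr"`; `$cv` holds the RMSECV
#'   curve and `$lv` the chosen component count. The coefficient vector
#'   spans all bands, as needed by CARS.
#' @export
fit_plsr <- function(spectra, y, max_lv = 15, n_folds = 5,
                     index = "index", units = "") {
  m <- spectra_matrix(spectra)
  grid <- attr(m, "wavelengths")
  stopifnot(length(y) == nrow(m))
  if (nrow(m) < 2 * n_folds) {
    stop("fit_plsr() needs at least 2 x n_folds samples", call. = FALSE)
  }
  rmsecv <- plsr_cv_rmse(m, y, max_lv, n_folds)
  lv <- which.min(rmsecv)
  fit <- nipals_pls(m, y, lv)
  lv <- fit$ncomp
  new_chemo_model(
    family = "plsr",
    intercept = fit$intercept[lv],
    coefficients = stats::setNames(fit$coef[, lv], format_wl(grid)),
    wavelengths = grid,
    index = index,
    units = units,
    lv = as.integer(lv),
    preprocessing = preprocessing_tag(spectra),
    cv = tibble::tibble(lv = seq_along(rmsecv), rmsecv = rmsecv)
  )
}

#' Predict index values from preprocessed spectra
#'
#' Evaluates the linear form `y = b0 + sum_j b_j X(lambda_j)` for every
#' sample. The spectra table must carry the model's preprocessing tag
#' (normally set by [snv_spectra()]); a mismatch is an error because the
#' coefficients are specific to that representation.
#'
#' @param object A `chemo_model`.
#' @param spectra A preprocessed spectra tibble.
#' @param tol Wavelength matching tolerance in nm.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per sample, named by
#'   `sample_id`.
#' @export
predict.chemo_model <- function(object, spectra, tol = 1, ...) {
  tag <- preprocessing_tag(spectra)
  if (!identical(tag, object$preprocessing)) {
    stop(sprintf(
      "preprocessing mismatch: model expects '%s' but spectra are '%s' %s",
      object$preprocessing, tag,
      "(apply snv_spectra() to the full spectrum first)"), call. = FALSE)
  }
  m <- spectra_matrix(spectra)
  grid <- attr(m, "wavelengths")
  bands <- vapply(object$wavelengths, nearest_band, integer(1),
                  grid = grid, tol = tol)
  pred <- drop(m[, bands, drop = FALSE] %*% object$coefficients) +
    object$intercept
  stats::setNames(as.numeric(pred), rownames(m))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a calibration model
#'
#' @param x A `chemo_model`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `wavelength_nm`,
#'   `estimate`.
#' @method tidy chemo_model
#' @export
tidy.chemo_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("X", names(x$coefficients), "nm")),
    wavelength_nm = c(NA_real_, x$wavelengths),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' One-row model summary
#'
#' @param x A `chemo_model`.
#' @param ... Unused.
#' @return A one-row tibble: family, index, units, number of wavelength
#'   terms, latent variables, preprocessing tag, provenance.
#' @method glance chemo_model
#' @export
glance.chemo_model <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    index = x$index,
    units = x$units,
    n_terms = length(x$coefficients),
    lv = x$lv,
    preprocessing = x$preprocessing,
    source = x$source
  )
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A `chemo_model`.
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the restored `chemo_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "chemo_model"))
  obj <- list(
    family = model$family,
    index = model$index,
    units = model$units,
    preprocessing = model$preprocessing,
    intercept = model$intercept,
    lv = if (is.na(model$lv)) NULL else model$lv,
    source = model$source,
    terms = data.frame(wavelength_nm = model$wavelengths,
                       coefficient = unname(model$coefficients))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_chemo_model(
    family = obj$family,
    intercept = obj$intercept,
    coefficients = stats::setNames(obj$terms$coefficient,
                                   format_wl(obj$terms$wavelength_nm)),
    wavelengths = obj$terms$wavelength_nm,
    index = obj$index,
    units = obj$units,
    lv = if (is.null(obj$lv)) NA_integer_ else as.integer(obj$lv),
    preprocessing = obj$preprocessing,
    source = obj$source
  )
}
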