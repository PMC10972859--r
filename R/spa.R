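# Successive projections algorithm (SPA). Deterministic forward selection
# of minimally collinear wavelengths: starting from each candidate band,
# the chain repeatedly adds the band whose column has maximal norm after
# orthogonal projection onto the complement of the span of the bands
# already chosen; candidate (chain, size) combinations are then scored by
# cross-validated MLR RMSE and the smallest size on the RMSE plateau wins.

# Build the projection chain for one starting column. X columns are
# projected against each selected column in turn (classic SPA update).
spa_chain <- function(X, start, max_size, tol = 1e-10) {
  P <- X
  chain <- integer(max_size)
  chain[1] <- as.integer(start)
  for (k in seq_len(max_size - 1)) {
    v <- P[, chain[k]]
    vv <- sum(v^2)
    if (vv < tol) return(chain[seq_len(k)])
    P <- P - outer(v, drop(crossprod(P, v)) / vv)
    norms <- colSums(P^2)
    norms[chain[seq_len(k)]] <- -1
    if (max(norms) < tol) return(chain[seq_len(k)])
    chain[k + 1] <- as.integer(which.max(norms))
  }
  chain
}

# k-fold cross-validated RMSE of an intercept + selected-columns MLR.
mlr_cv_rmse <- function(X, y, cols, n_folds) {
  n <- nrow(X)
  folds <- cv_folds(n, n_folds)
  press <- numeric(n)
  D <- cbind(1, X[, cols, drop = FALSE])
  for (f in seq_len(max(folds))) {
    hold <- folds == f
    fit <- stats::lm.fit(D[!hold, , drop = FALSE], y[!hold])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    press[hold] <- (D[hold, , drop = FALSE] %*% beta - y[hold])^2
  }
  sqrt(mean(press))
}

#' SPA feature-wavelength selection
#'
#' Phase 1 builds a projection chain of length `max_size` from every
#' candidate start wavelength. Phase 2 scores each (start, size)
#' combination by `n_folds`-fold cross-validated MLR RMSE on the
#' calibration set. The returned size is the smallest on the RMSE
#' plateau: chain growth stops once the relative improvement of the
#' best-achievable RMSE falls below `plateau_tol` (or the RMSE is
#' numerically zero); within that size the best-scoring chain wins.
#' Fully deterministic.
#'
#' @param spectra Calibration spectra tibble (normally SNV-preprocessed).
#' @param y Reference index values, aligned with `spectra`.
#' @param max_size Largest subset size considered; must be smaller than
#'   both `n - 1` and the band count.
#' @param n_folds Cross-validation folds for the MLR scoring.
#' @param plateau_tol Relative-improvement threshold that defines the
#'   plateau (default 1%).
#' @return A `selection_result` with the selected band indices and nm,
#'   the per-size best-RMSE trajectory (`size`, `rmse`), and the chosen
#'   size in `$best`.
#' @export
spa_select <- function(spectra, y, max_size = 20, n_folds = 5,
                       plateau_tol = 0.01) {
  X <- spectra_matrix(spectra)
  grid <- attr(X, "wavelengths")
  stopifnot(length(y) == nrow(X))
  n <- nrow(X)
  B <- ncol(X)
  if (max_size >= min(n - 1, B)) {
    stop("max_size must be smaller than min(n_samples - 1, n_bands)",
         call. = FALSE)
  }
  chains <- lapply(seq_len(B), function(s) spa_chain(X, s, max_size))
  rmse <- matrix(Inf, B, max_size)
  for (s in seq_len(B)) {
    ch <- chains[[s]]
    for (k in seq_along(ch)) {
      if (k + 2 > n) break  # need more samples than coefficients
      rmse[s, k] <- mlr_cv_rmse(X, y, ch[seq_len(k)], n_folds)
    }
  }
  best_per_size <- apply(rmse, 2, min)
  valid_sizes <- which(is.finite(best_per_size))
  if (length(valid_sizes) == 0) stop("SPA: no scorable subset",
                                     call. = FALSE)
  size <- max(valid_sizes)
  for (k in valid_sizes) {
    if (best_per_size[k] < 1e-10) { size <- k; break }
    if (k < max(valid_sizes)) {
      gain <- (best_per_size[k] - best_per_size[k + 1]) / best_per_size[k]
      if (gain < plateau_tol) { size <- k; break }
    }
  }
  start <- which.min(rmse[, size])
  sel <- chains[[start]][seq_len(size)]
  new_selection_result(
    method = "spa",
    indices = sort(sel),
    wavelengths = grid[sort(sel)],
    trajectory = tibble::tibble(size = valid_sizes,
                                rmse = best_per_size[valid_sizes]),
    best = size,
    extra = list(start = start, chain = sel)
  )
}
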