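# Independent brute-force oracles used by several test files.

# Independent brute-force Kennard-Stone max-min oracle on a precomputed
# joint distance matrix; written against the algorithm definition, not
# the implementation.
spxy_oracle <- function(spectra, reference, n_cal) {
  X <- spectra_matrix(snv_spectra(spectra))
  idx_cols <- intersect(c("ssc", "firmness", "lstar", "astar", "bstar"),
                        names(reference))
  Y <- scale(as.matrix(reference[idx_cols]))
  dx <- as.matrix(dist(X))
  dy <- as.matrix(dist(Y))
  d <- dx / max(dx) + dy / max(dy)
  n <- nrow(d)
  pairs <- which(d == max(d), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  sel <- as.integer(pairs[order(pairs[, 1], pairs[, 2])[1], ])
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    score <- vapply(rest, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(score)])  # which.max: first = lowest id
  }
  sel
}

# Exhaustive oracle: every start wavelength, every size, chains built by
# explicit least-squares residual projection (lm.fit), scored with the
# same CV RMSE function.
spa_oracle <- function(X, y, max_size, n_folds, plateau_tol = 0.01) {
  B <- ncol(X)
  chain_for <- function(start) {
    chain <- start
    for (k in seq_len(max_size - 1)) {
      rest <- setdiff(seq_len(B), chain)
      norms <- vapply(rest, function(j) {
        r <- stats::lm.fit(X[, chain, drop = FALSE], X[, j])$residuals
        sum(r^2)
      }, numeric(1))
      if (max(norms) < 1e-10) break
      chain <- c(chain, rest[which.max(norms)])
    }
    chain
  }
  chains <- lapply(seq_len(B), chain_for)
  rmse <- matrix(Inf, B, max_size)
  for (s in seq_len(B)) {
    for (k in seq_along(chains[[s]])) {
      rmse[s, k] <- kiwispec:::mlr_cv_rmse(X, y, chains[[s]][seq_len(k)],
                                           n_folds)
    }
  }
  best <- apply(rmse, 2, min)
  sizes <- which(is.finite(best))
  size <- max(sizes)
  for (k in sizes) {
    if (best[k] < 1e-10) { size <- k; break }
    if (k < max(sizes) &&
        (best[k] - best[k + 1]) / best[k] < plateau_tol) {
      size <- k
      break
    }
  }
  start <- which.min(rmse[, size])
  chains[[start]][seq_len(size)]
}

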