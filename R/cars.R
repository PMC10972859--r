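# Competitive adaptive reweighted sampling (CARS). Monte Carlo wavelength
# selection: at each sampling run a PLSR is fitted on a random subset of
# calibration samples, wavelengths compete through the absolute values of
# their regression coefficients, an exponentially decreasing function
# (EDF) forces the retained count down, and adaptive reweighted sampling
# realises the retained set; the run with the lowest cross-validated RMSE
# wins.

# EDF retained-count schedule: r_i = a e^{-k i} with r_1 = 1 and
# r_N = 2/B, i.e. k = log(B/2)/(N-1), a = e^k.
cars_edf_counts <- function(n_bands, n_runs) {
  n_bands <- as.integer(n_bands)
  if (n_runs < 2) return(rep(n_bands, n_runs))
  k <- log(n_bands / 2) / (n_runs - 1)
  r <- exp(k) * exp(-k * seq_len(n_runs))
  as.integer(pmax(2L, pmin(n_bands, as.integer(round(r * n_bands)))))
}

# Choose the latent-variable count by k-fold RMSECV and return the
# coefficient vector at that count (plus the minimum RMSECV itself).
pls_cv_pick <- function(X, y, max_lv, n_folds) {
  rmse <- plsr_cv_rmse(X, y, max_lv, n_folds)
  lv <- which.min(rmse)
  fit <- nipals_pls(X, y, lv)
  list(coef = fit$coef[, fit$ncomp], rmsecv = rmse[lv], lv = fit$ncomp)
}

#' CARS feature-wavelength selection
#'
#' Runs `n_runs` Monte Carlo sampling runs. Run `i`: (a) draw
#' `mc_ratio x n` calibration samples without replacement; (b) fit a PLSR
#' on the currently retained wavelengths (latent variables chosen by
#' `n_folds`-fold RMSECV, capped at `max_lv`); (c) rank wavelengths by
#' the absolute regression coefficients |b|; (d) the exponentially
#' decreasing function (`r_1 = 1`, `r_N = 2/B`) fixes the retained count
#' at `round(r_i B)`; (e) adaptive reweighted sampling realises that set:
#' a weighted draw without replacement with probability proportional to
#' |b|, so the retained count follows the EDF exactly while weak
#' wavelengths are competitively eliminated; (f) record the
#' `n_folds`-fold RMSECV of a PLSR on the realised set over the full
#' calibration set. The wavelength set of the
#' run with minimum RMSECV is returned. Deterministic given
#' `(data, seed)`.
#'
#' @param spectra Calibration spectra tibble (normally SNV-preprocessed).
#' @param y Reference index values, aligned with `spectra`.
#' @param n_runs Monte Carlo sampling runs (default 50).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for the Monte Carlo draws (required).
#' @param mc_ratio Fraction of calibration samples drawn per run.
#' @param max_lv Latent-variable cap for the internal PLSR fits.
#' @param max_select Upper bound on the size of the returned set: the
#'   argmin is taken over runs whose realised set has at most this many
#'   wavelengths (use `n_cal - 2` when the set will feed an MLR).
#' @return A `selection_result` with the selected band indices and nm,
#'   the per-run trajectory (`run`, `n_edf`, `n_retained`, `rmsecv`), the
#'   argmin run and the seed.
#' @export
cars_select <- function(spectra, y, n_runs = 50, n_folds = 5, seed,
                        mc_ratio = 0.8, max_lv = 10, max_select = Inf) {
  if (missing(seed)) stop("cars_select() requires an explicit seed",
                          call. = FALSE)
  X <- spectra_matrix(spectra)
  grid <- attr(X, "wavelengths")
  stopifnot(length(y) == nrow(X))
  n <- nrow(X)
  B <- ncol(X)
  if (n < 2 * n_folds) {
    stop("cars_select() needs at least 2 x n_folds calibration samples",
         call. = FALSE)
  }
  edf <- cars_edf_counts(B, n_runs)
  n_sub <- max(2L, round(mc_ratio * n))
  with_seed(seed, {
    retained <- seq_len(B)
    runs <- vector("list", n_runs)
    sets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      sub <- sample.int(n, n_sub)
      fit <- pls_cv_pick(X[sub, retained, drop = FALSE], y[sub],
                         max_lv, n_folds)
      w <- abs(fit$coef)
      keep_n <- min(edf[i], length(retained))
      if (all(w == 0)) w <- rep(1, length(w))
      # EDF fixes the retained count; ARS realises the set by a weighted
      # draw without replacement, prob proportional to |b|, so strong
      # coefficients almost surely survive while weak ones rarely do
      draw <- sample(seq_along(retained), size = keep_n, prob = w)
      retained <- sort(retained[draw])
      if (length(retained) < 2) {
        warning(sprintf(
          "CARS stopped at run %d: fewer than 2 wavelengths retained", i))
        runs <- runs[seq_len(i - 1)]
        sets <- sets[seq_len(i - 1)]
        break
      }
      cvfit <- pls_cv_pick(X[, retained, drop = FALSE], y, max_lv, n_folds)
      runs[[i]] <- tibble::tibble(
        run = i, n_edf = edf[i], n_retained = length(retained),
        rmsecv = cvfit$rmsecv)
      sets[[i]] <- retained
    }
    trajectory <- dplyr::bind_rows(runs)
    valid <- is.finite(trajectory$rmsecv) &
      trajectory$n_retained <= max_select
    if (!any(valid)) stop("CARS: no run produced a finite RMSECV",
                          call. = FALSE)
    best <- trajectory$run[valid][which.min(trajectory$rmsecv[valid])]
    sel <- sets[[best]]
    new_selection_result(
      method = "cars",
      indices = sel,
      wavelengths = grid[sel],
      trajectory = trajectory,
      best = best,
      seed = seed
    )
  })
}
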