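# Synthetic-data generator. Emulates the study conditions: four maturity
# stages of 50 fruit each with stage-specific SSC ranges, reflectance
# spectra with absorption features near 675 nm (chlorophyll) and 980 nm
# (water), indices coupled linearly to latent component concentrations,
# per-sample multiplicative/additive scatter (exactly the class SNV
# removes) and additive Gaussian noise. Every draw is reproducible from
# (config, seed) and ships its ground truth for recovery tests.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic generator. The defaults encode
#' the emulated study: 4 maturity stages x 50 samples, stage SSC ranges
#' 4.63-5.73, 5.90-7.30, 6.50-9.20 and 9.20-12.20 °Brix, endmember
#' absorption peaks at 675 nm (chlorophyll, sd 25 nm), 980 nm (water,
#' sd 45 nm) and 910 nm (sugar-associated NIR band, sd 60 nm), scatter
#' gain U(0.9, 1.1) and offset U(-0.05, 0.05), and spectral noise
#' sd 0.002 reflectance units.
#'
#' @param n_per_stage Samples per maturity stage (>= 2).
#' @param stage_ssc_ranges 4 x 2 matrix of per-stage SSC ranges (°Brix).
#' @param peak_centers,peak_widths Named numeric vectors (nm) for the
#'   endmember absorption profiles.
#' @param amplitudes Signed endmember loadings per unit concentration;
#'   negative values produce reflectance dips.
#' @param gain_range,offset_range Per-sample multiplicative/additive
#'   scatter ranges.
#' @param noise_sd Spectral noise sd (reflectance units, >= 0).
#' @param index_noise_sd Named measurement-noise sds for the five indices.
#' @param seed Default seed used by the stochastic generator calls.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_stage = 50,
                       stage_ssc_ranges = rbind(
                         unripe = c(4.63, 5.73),
                         semi_ripe = c(5.90, 7.30),
                         ripe = c(6.50, 9.20),
                         over_ripe = c(9.20, 12.20)),
                       peak_centers = c(chlorophyll = 675, water = 980,
                                        sugar = 910),
                       peak_widths = c(chlorophyll = 25, water = 45,
                                       sugar = 60),
                       amplitudes = c(chlorophyll = -0.25, water = -0.18,
                                      sugar = -0.02),
                       gain_range = c(0.9, 1.1),
                       offset_range = c(-0.05, 0.05),
                       noise_sd = 0.002,
                       index_noise_sd = c(ssc = 0.10, firmness = 0.40,
                                          lstar = 1.00, astar = 0.60,
                                          bstar = 1.00),
                       seed = 101L) {
  stopifnot(
    n_per_stage >= 1,
    is.matrix(stage_ssc_ranges), ncol(stage_ssc_ranges) == 2,
    all(stage_ssc_ranges[, 2] >= stage_ssc_ranges[, 1]),
    length(peak_centers) == length(peak_widths),
    length(peak_centers) == length(amplitudes),
    all(peak_widths > 0),
    diff(gain_range) >= 0, diff(offset_range) >= 0,
    noise_sd >= 0,
    all(index_noise_sd >= 0)
  )
  structure(list(
    n_per_stage = as.integer(n_per_stage),
    stage_ssc_ranges = stage_ssc_ranges,
    peak_centers = peak_centers,
    peak_widths = peak_widths,
    amplitudes = amplitudes,
    gain_range = gain_range,
    offset_range = offset_range,
    noise_sd = noise_sd,
    index_noise_sd = index_noise_sd,
    # index = intercept + slopes %*% concentrations (+ noise); slopes are
    # per latent component (sugar-tracking maturity u, chlorophyll, water)
    coupling = list(
      ssc      = c(intercept = 0,    u = 1,    chl = 0,  wat = 0),
      firmness = c(intercept = 6,    u = 0,    chl = 15, wat = 0),
      lstar    = c(intercept = 29.35, u = 0,   chl = 0,  wat = 14),
      astar    = c(intercept = 5.5,  u = 0.45, chl = 0,  wat = 0),
      bstar    = c(intercept = 9.5,  u = 1.3,  chl = 0,  wat = 0)
    ),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Smooth low-order polynomial baseline in [0.2, 0.8] over the grid span.
sim_baseline <- function(grid) {
  t <- (grid - min(grid)) / diff(range(grid))
  0.25 + 0.9 * t - 0.45 * t^2
}

#' Endmember absorption profiles
#'
#' Builds the smooth, non-negative component profiles (Gaussian bumps,
#' unit peak height) used by the generator: chlorophyll peaking at the
#' grid point nearest 675 nm, water nearest 980 nm, and a broad
#' sugar-associated band near 910 nm. Deterministic given the config.
#'
#' @param grid Wavelength grid.
#' @param config A [sim_config()].
#' @return Components x bands matrix with rownames per component.
#' @export
make_endmembers <- function(grid = default_wavelength_grid(),
                            config = sim_config()) {
  validate_grid(grid)
  ctr <- config$peak_centers
  bad <- ctr < min(grid) | ctr > max(grid)
  if (any(bad)) {
    stop("endmember peak(s) outside the grid span: ",
         paste(sprintf("%s (%g nm)", names(ctr)[bad], ctr[bad]),
               collapse = ", "), call. = FALSE)
  }
  E <- t(vapply(seq_along(ctr), function(k) {
    exp(-0.5 * ((grid - ctr[k]) / config$peak_widths[k])^2)
  }, numeric(length(grid))))
  rownames(E) <- names(ctr)
  colnames(E) <- format_wl(grid)
  E
}

#' Simulate sample spectra and reference physicochemical values
#'
#' For each stage, maturity scores are drawn from the stage's SSC range;
#' latent concentrations (sugar-tracking `u`, chlorophyll decreasing with
#' maturity, water mildly increasing) drive both the spectra
#' (`gain x (baseline + sum amp_k conc_k endmember_k) + offset + noise`)
#' and the reference indices (affine in the concentrations plus
#' measurement noise). By construction stage-mean SSC increases and
#' stage-mean firmness decreases with maturity.
#'
#' @param config A [sim_config()].
#' @param grid Wavelength grid.
#' @param seed Seed (defaults to `config$seed`).
#' @return A list: `spectra` (tibble, `sample_id` + 256 band columns),
#'   `reference` (tibble, `sample_id`, `stage`, the five indices), and
#'   `truth` (latent concentrations, coupling, endmembers, informative
#'   band indices, scatter gains/offsets).
#' @export
simulate_samples <- function(config = sim_config(),
                             grid = default_wavelength_grid(),
                             seed = config$seed) {
  if (config$n_per_stage < 2) {
    stop("n_per_stage must be >= 2 (downstream statistics need a sd)",
         call. = FALSE)
  }
  validate_grid(grid)
  E <- make_endmembers(grid, config)
  base <- sim_baseline(grid)
  rng <- config$stage_ssc_ranges
  n_stage <- nrow(rng)
  n <- config$n_per_stage * n_stage
  lo <- min(rng)
  hi <- max(rng)
  with_seed(seed, {
    stage <- rep(rownames(rng), each = config$n_per_stage)
    u <- unlist(lapply(seq_len(n_stage), function(s) {
      stats::runif(config$n_per_stage, rng[s, 1], rng[s, 2])
    }))
    m <- (u - lo) / (hi - lo)
    conc <- cbind(
      u = u,
      chl = pmax(1.2 - 0.8 * m + stats::rnorm(n, 0, 0.05), 0),
      wat = pmax(0.8 + 0.15 * m + stats::rnorm(n, 0, 0.08), 0)
    )
    gain <- stats::runif(n, config$gain_range[1], config$gain_range[2])
    offset <- stats::runif(n, config$offset_range[1],
                           config$offset_range[2])
    # endmember rows are keyed chlorophyll/water/sugar; concentrations map
    # sugar <- u
    conc_spec <- conc[, c("chl", "wat", "u"), drop = FALSE]
    amp <- config$amplitudes[c("chlorophyll", "water", "sugar")]
    pure <- matrix(base, n, length(grid), byrow = TRUE) +
      (conc_spec %*% (amp * E[c("chlorophyll", "water", "sugar"), ]))
    spectra <- gain * pure + offset +
      matrix(stats::rnorm(n * length(grid), 0, config$noise_sd), n)
    ids <- sprintf("S%03d", seq_len(n))
    ref <- tibble::tibble(
      sample_id = ids,
      stage = factor(stage, levels = rownames(rng))
    )
    for (idx in .kiwi_indices) {
      cp <- config$coupling[[idx]]
      ref[[idx]] <- cp["intercept"] + drop(conc %*% cp[c("u", "chl", "wat")]) +
        stats::rnorm(n, 0, config$index_noise_sd[[idx]])
    }
    informative <- which(apply(E / apply(E, 1, max), 2, max) > 0.5)
    list(
      spectra = as_spectra_tibble(spectra, grid, ids),
      reference = ref,
      truth = list(
        concentrations = tibble::tibble(sample_id = ids,
                                        u = conc[, "u"],
                                        chl = conc[, "chl"],
                                        wat = conc[, "wat"]),
        coupling = config$coupling,
        endmembers = E,
        baseline = base,
        informative_bands = unname(informative),
        gain = gain,
        offset = offset
      )
    )
  })
}

#' Simulate a raw hypercube plus dark/white reference frames
#'
#' Places an elliptical "fruit" carrying the given reflectance spectrum
#' (with per-pixel gain and noise) on a dark background, then converts
#' reflectance to raw counts as `raw = dark + R x (white - dark)`, so
#' reflectance calibration inverts the construction exactly in the
#' noiseless limit.
#'
#' @param spectrum Reflectance spectrum on `grid`.
#' @param shape `c(H, W)` image size, each >= 8.
#' @param config A [sim_config()] (supplies noise level and seed).
#' @param grid Wavelength grid.
#' @param seed Seed (defaults to `config$seed`).
#' @param pixel_gain_range Per-pixel multiplicative gain range.
#' @return A list: `raw`, `white`, `dark` ([hypercube()]s of kind
#'   `"raw"`), and `mask` (the ground-truth fruit mask).
#' @export
simulate_cube <- function(spectrum, shape = c(48, 48),
                          config = sim_config(),
                          grid = default_wavelength_grid(),
                          seed = config$seed,
                          pixel_gain_range = c(0.95, 1.05)) {
  validate_grid(grid)
  stopifnot(length(spectrum) == length(grid))
  if (length(shape) != 2 || any(shape < 8)) {
    stop("cube shape must be H x W with both dimensions >= 8",
         call. = FALSE)
  }
  H <- shape[1]
  W <- shape[2]
  B <- length(grid)
  t <- (grid - min(grid)) / diff(range(grid))
  white_level <- 3500 * (0.6 + 0.4 * t)
  dark_level <- rep(120, B)
  rc <- expand.grid(row = seq_len(H), col = seq_len(W))
  mask <- matrix(((rc$row - (H + 1) / 2) / (0.38 * H))^2 +
                 ((rc$col - (W + 1) / 2) / (0.38 * W))^2 <= 1, H, W)
  with_seed(seed, {
    refl <- array(0.03, c(H, W, B))
    idx <- which(mask)
    g <- stats::runif(length(idx), pixel_gain_range[1],
                      pixel_gain_range[2])
    fg <- outer(g, spectrum) +
      matrix(stats::rnorm(length(idx) * B, 0, config$noise_sd),
             length(idx))
    flat <- matrix(refl, H * W, B)
    flat[idx, ] <- fg
    bg_noise <- matrix(stats::rnorm((H * W - length(idx)) * B, 0,
                                    config$noise_sd / 2),
                       H * W - length(idx))
    flat[-idx, ] <- flat[-idx, , drop = FALSE] + bg_noise
    refl <- array(flat, c(H, W, B))
    white <- array(rep(white_level, each = H * W), c(H, W, B))
    dark <- array(rep(dark_level, each = H * W), c(H, W, B))
    raw <- dark + refl * (white - dark)
    list(
      raw = hypercube(raw, grid, kind = "raw"),
      white = hypercube(white, grid, kind = "raw"),
      dark = hypercube(dark, grid, kind = "raw"),
      mask = mask
    )
  })
}
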