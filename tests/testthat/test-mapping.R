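constant_cube <- function(s, H = 10, W = 10,
                          wl = default_wavelength_grid()) {
  hypercube(array(rep(s, each = H * W), c(H, W, length(s))), wl,
            kind = "reflectance", mask = matrix(TRUE, H, W))
}

test_that("a constant cube maps to the spectrum's prediction everywhere", {
  wl <- default_wavelength_grid()
  withr::with_seed(3, s <- runif(256, 0.2, 0.8))
  m <- published_model("SSC")
  pm <- predict_map(constant_cube(s, wl = wl), m)
  z <- as_preprocessed(as_spectra_tibble(matrix(snv(s), 1), wl, "px"))
  want <- unname(predict(m, z))
  expect_true(all(abs(pm$values - want) < 1e-9))
  expect_identical(pm$units, "°Brix")
})

test_that("a crafted SNV-fixed-point spectrum recovers the intercept", {
  wl <- default_wavelength_grid()
  m <- published_model("firmness")
  bands <- vapply(m$wavelengths, nearest_band, integer(1), grid = wl)
  s <- snv_fixed_point_with_zeros(256, bands)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(s^2)), 1, tolerance = 1e-12)
  pm <- predict_map(constant_cube(s, 8, 8, wl), m)
  expect_equal(unique(round(pm$values[pm$mask], 6)), 235.6)
})

test_that("mapping equals looping predict over individual pixel spectra", {
  wl <- default_wavelength_grid()
  sim <- tiny_sim(2, seed = 8)
  s <- as.numeric(spectra_matrix(sim$spectra)[1, ])
  cb <- simulate_cube(s, c(12, 12), sim_config(), wl, seed = 4)
  refl <- calibrate_reflectance(cb$raw, cb$white, cb$dark)
  m <- published_model("b*")
  pm <- predict_map(refl, m, mask = cb$mask)
  flat <- matrix(refl$data, 144, 256)
  idx <- which(cb$mask)
  for (i in idx[c(1, 5, 20)]) {
    z <- as_preprocessed(as_spectra_tibble(
      matrix(snv(flat[i, ]), 1), wl, "px"))
    expect_equal(unname(pm$values[i]), unname(predict(m, z)),
                 tolerance = 1e-10)
  }
})

test_that("map of the mean differs from mean of the map (SNV nonlinearity)", {
  wl <- default_wavelength_grid()
  sim <- tiny_sim(2, seed = 8)
  s <- as.numeric(spectra_matrix(sim$spectra)[1, ])
  cb <- simulate_cube(s, c(12, 12), sim_config(), wl, seed = 4)
  refl <- calibrate_reflectance(cb$raw, cb$white, cb$dark)
  m <- published_model("SSC")
  pm <- predict_map(refl, m, mask = cb$mask)
  mean_of_map <- mean(pm$values[pm$mask])
  z_mean <- as_preprocessed(as_spectra_tibble(
    matrix(snv(mean_spectrum(refl, cb$mask)), 1), wl, "mean"))
  map_of_mean <- unname(predict(m, z_mean))
  # documented discrepancy: SNV is nonlinear, so these do not coincide
  expect_gt(abs(mean_of_map - map_of_mean), 1e-8)
})

test_that("constant-spectrum pixels are dropped with a count message", {
  wl <- seq(400, 1000, length.out = 16)
  withr::with_seed(5, s <- runif(16, 0.3, 0.7))
  cube <- constant_cube(s, 4, 4, wl)
  cube$data[2, 2, ] <- 0.5
  m <- kiwispec:::new_chemo_model(
    family = "mlr", intercept = 0,
    coefficients = c("400" = 1), wavelengths = 400,
    index = "ssc", units = "°Brix")
  expect_message(pm <- predict_map(cube, m), "1 constant")
  expect_false(pm$mask[2, 2])
  expect_true(is.na(pm$values[2, 2]))
})

test_that("rendering is pure and respects a shared range", {
  vals <- matrix(NA_real_, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[2:3, 2:3] <- TRUE
  vals[mask] <- 5
  pm <- structure(list(values = vals, mask = mask, index = "ssc",
                       units = "°Brix", model = "mlr"),
                  class = "prediction_map")
  r <- render_pseudocolor(pm, range = c(0, 10), n_colors = 51)
  # constant map at the range midpoint -> uniform mid-colormap colour
  mid <- grDevices::col2rgb(grDevices::hcl.colors(51, "viridis")[26]) / 255
  px <- r$rgb[2, 2, ]
  expect_equal(unname(px), unname(drop(mid)), tolerance = 1e-9)
  expect_equal(r$rgb[2, 2, ], r$rgb[3, 3, ])
  # purity: identical inputs give identical renderings
  r2 <- render_pseudocolor(pm, range = c(0, 10), n_colors = 51)
  expect_identical(r, r2)
  # same value under the same explicit range -> same colour across maps
  pm2 <- pm
  pm2$values[mask] <- c(5, 5, 0, 10)
  rr <- render_pseudocolor(pm2, range = c(0, 10), n_colors = 51)
  expect_identical(rr$rgb[2, 2, ], r$rgb[2, 2, ])
  expect_error(render_pseudocolor(pm, range = c(3, 3)), "degenerate")
})

test_that("out-of-range values clip to the colormap endpoints", {
  vals <- matrix(c(-5, 50, 2, 8), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  pm <- structure(list(values = vals, mask = mask, index = "ssc",
                       units = "°Brix", model = "mlr"),
                  class = "prediction_map")
  r <- render_pseudocolor(pm, range = c(0, 10), n_colors = 11)
  pal <- grDevices::col2rgb(grDevices::hcl.colors(11, "viridis")) / 255
  expect_equal(unname(r$rgb[1, 1, ]), unname(pal[, 1]))
  expect_equal(unname(r$rgb[2, 1, ]), unname(pal[, 11]))
})

test_that("stage-series SSC maps shift monotonically in colour coordinate", {
  wl <- default_wavelength_grid()
  sim <- simulate_samples(sim_config(n_per_stage = 10), seed = 27)
  z <- snv_spectra(sim$spectra)
  m <- fit_mlr(z, sim$reference$ssc, published_wavelengths("ssc", "spa"),
               index = "ssc", units = "°Brix")
  sm <- spectra_matrix(sim$spectra)
  stages <- levels(sim$reference$stage)
  maps <- lapply(seq_along(stages), function(k) {
    i <- which(sim$reference$stage == stages[k])[1]
    cb <- simulate_cube(sm[i, ], c(16, 16), sim_config(), wl,
                        seed = 50 + k)
    refl <- calibrate_reflectance(cb$raw, cb$white, cb$dark)
    predict_map(refl, m, mask = cb$mask)
  })
  shared <- map_display_range(maps)
  mean_bin <- vapply(maps, function(pm) {
    v <- (pm$values[pm$mask] - shared[1]) / diff(shared)
    mean(pmin(pmax(v, 0), 1))
  }, numeric(1))
  expect_true(all(diff(mean_bin) > 0))
})

test_that("write_map emits PNG, CSV and JSON sidecar", {
  wl <- seq(400, 1000, length.out = 8)
  withr::with_seed(2, s <- runif(8, 0.2, 0.8))
  m <- kiwispec:::new_chemo_model(
    family = "mlr", intercept = 1,
    coefficients = c("400" = 1), wavelengths = 400,
    index = "firmness", units = "kg·cm⁻²")
  pm <- predict_map(constant_cube(s, 6, 6, wl), m)
  r <- render_pseudocolor(pm, range = c(0, 3))
  path <- file.path(withr::local_tempdir(), "map")
  write_map(r, pm, path)
  expect_true(file.exists(paste0(path, ".png")))
  expect_true(file.exists(paste0(path, "_values.csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$units, "kg·cm⁻²")
  expect_equal(unlist(meta$range), c(0, 3))
})
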