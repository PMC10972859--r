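test_that("endmembers peak at the grid points nearest 675 and 980 nm", {
  wl <- default_wavelength_grid()
  E <- make_endmembers(wl, sim_config())
  expect_gte(nrow(E), 2)
  expect_true(all(E >= 0))
  expect_identical(unname(which.max(E["chlorophyll", ])),
                   unname(which.min(abs(wl - 675))))
  expect_identical(unname(which.max(E["water", ])),
                   unname(which.min(abs(wl - 980))))
})

test_that("an endmember peak outside the grid span is rejected by name", {
  cfg <- sim_config(peak_centers = c(chlorophyll = 675, water = 2000,
                                     sugar = 910))
  expect_error(make_endmembers(default_wavelength_grid(), cfg), "water")
})

test_that("the default design yields 200 samples x 256 bands", {
  sim <- simulate_samples(sim_config())
  expect_identical(dim(spectra_matrix(sim$spectra)), c(200L, 256L))
  expect_identical(nrow(sim$reference), 200L)
  expect_identical(as.integer(table(sim$reference$stage)),
                   rep(50L, 4))
})

test_that("generator outputs are reproducible bit-for-bit from (config, seed)", {
  a <- simulate_samples(sim_config(n_per_stage = 4), seed = 7)
  b <- simulate_samples(sim_config(n_per_stage = 4), seed = 7)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$reference, b$reference)
  s <- as.numeric(spectra_matrix(a$spectra)[1, ])
  c1 <- simulate_cube(s, c(12, 12), sim_config(), seed = 3)
  c2 <- simulate_cube(s, c(12, 12), sim_config(), seed = 3)
  expect_identical(c1$raw$data, c2$raw$data)
})

test_that("noiseless spectra lie in the span of baseline and endmembers", {
  cfg <- sim_config(n_per_stage = 4, noise_sd = 0,
                    gain_range = c(1, 1), offset_range = c(0, 0))
  wl <- default_wavelength_grid()
  sim <- simulate_samples(cfg, wl, seed = 2)
  E <- make_endmembers(wl, cfg)
  basis <- cbind(sim$truth$baseline, t(E))
  m <- t(spectra_matrix(sim$spectra))  # bands x samples
  resid <- m - basis %*% qr.coef(qr(basis), m)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("stage-wise SSC means increase and firmness means decrease", {
  sim <- simulate_samples(sim_config(), seed = 101)
  ssc_means <- tapply(sim$reference$ssc, sim$reference$stage, mean)
  firm_means <- tapply(sim$reference$firmness, sim$reference$stage, mean)
  expect_true(all(diff(ssc_means) > 0))
  expect_true(all(diff(firm_means) < 0))
})

test_that("degenerate generator inputs are rejected", {
  expect_error(simulate_samples(sim_config(n_per_stage = 1)),
               "n_per_stage")
  expect_error(simulate_cube(rep(0.5, 256), shape = c(0, 16)),
               "shape")
})

test_that("reflectance calibration inverts the cube construction when noiseless", {
  cfg <- sim_config(noise_sd = 0)
  wl <- default_wavelength_grid()
  s <- 0.2 + 0.5 * seq(0, 1, length.out = 256)
  cb <- simulate_cube(s, c(16, 16), cfg, wl, seed = 5,
                      pixel_gain_range = c(1, 1))
  refl <- calibrate_reflectance(cb$raw, cb$white, cb$dark)
  flat <- matrix(refl$data, 256, 256)
  err <- max(abs(sweep(flat[which(cb$mask), , drop = FALSE], 2, s)))
  expect_lt(err, 1e-12)
})

test_that("the generator's scatter model is exactly the class SNV removes", {
  # SNV of the scattered noiseless spectrum must equal SNV of the
  # unscattered one by affine invariance
  cfg <- sim_config(n_per_stage = 3, noise_sd = 0, seed = 11)
  sim0 <- simulate_samples(cfg)
  cfg_flat <- sim_config(n_per_stage = 3, noise_sd = 0, seed = 11,
                         gain_range = c(1, 1), offset_range = c(0, 0))
  sim_flat <- simulate_samples(cfg_flat)
  z_scatter <- spectra_matrix(snv_spectra(sim0$spectra))
  z_flat <- spectra_matrix(snv_spectra(sim_flat$spectra))
  expect_equal(unclass(z_scatter), unclass(z_flat), tolerance = 1e-10,
               ignore_attr = TRUE)
})
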