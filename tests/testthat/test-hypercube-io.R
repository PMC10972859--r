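make_test_cube <- function(H = 6, W = 5, B = 4, seed = 3) {
  withr::with_seed(seed, {
    wl <- sort(runif(B, 400, 1000))
    hypercube(array(runif(H * W * B), c(H, W, B)), wl,
              kind = "reflectance")
  })
}

test_that("ENVI write/read round trip reproduces data and wavelengths exactly", {
  cube <- make_test_cube()
  path <- withr::local_tempfile()
  write_envi(cube, path)
  back <- read_envi(path, kind = "reflectance")
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths, cube$wavelengths)
})

test_that("BIL, BIP and BSQ interleaves read back identically", {
  cube <- make_test_cube()
  d <- dim(cube$data)
  write_interleave <- function(interleave, perm) {
    path <- withr::local_tempfile(.local_envir = parent.frame(2))
    writeLines(c(
      "ENVI",
      sprintf("samples = %d", d[2]),
      sprintf("lines = %d", d[1]),
      sprintf("bands = %d", d[3]),
      "data type = 5",
      sprintf("interleave = %s", interleave),
      "byte order = 0",
      sprintf("wavelength = { %s }",
              paste(sprintf("%.17g", cube$wavelengths), collapse = ", "))
    ), paste0(path, ".hdr"))
    con <- file(path, "wb")
    writeBin(as.vector(aperm(cube$data, perm)), con, size = 8,
             endian = "little")
    close(con)
    path
  }
  # order written: fastest axis first in aperm result
  for (case in list(list("bil", c(2, 3, 1)), list("bip", c(3, 2, 1)),
                    list("bsq", c(2, 1, 3)))) {
    path <- write_interleave(case[[1]], case[[2]])
    back <- read_envi(path, kind = "reflectance")
    expect_identical(back$data, cube$data, label = case[[1]])
  }
})

test_that("reflectance correction satisfies its defining identities", {
  wl <- c(500, 600, 700)
  geom <- c(4, 4, 3)
  dark <- array(100, geom)
  white <- array(900, geom)
  as_cube <- function(a) hypercube(a, wl, kind = "raw")
  r_white <- calibrate_reflectance(as_cube(white), white, dark)
  expect_true(all(r_white$data == 1))
  r_dark <- calibrate_reflectance(as_cube(dark), white, dark)
  expect_true(all(r_dark$data == 0))
  raw <- array(50, geom)
  r <- calibrate_reflectance(as_cube(raw), array(90, geom),
                             array(10, geom))
  expect_equal(unique(as.vector(r$data)), 0.5)
  # scale-freeness: multiplying all frames by c > 0 changes nothing
  r2 <- calibrate_reflectance(as_cube(raw * 7), array(90, geom) * 7,
                              array(10, geom) * 7)
  expect_equal(r2$data, r$data)
})

test_that("geometry mismatches are rejected naming the axis", {
  wl <- c(500, 600, 700)
  raw <- hypercube(array(1, c(4, 4, 3)), wl, kind = "raw")
  expect_error(
    calibrate_reflectance(raw, array(2, c(4, 5, 3)), array(0, c(4, 4, 3))),
    "samples")
  expect_error(
    calibrate_reflectance(raw, array(2, c(4, 4, 3)), array(0, c(3, 4, 3))),
    "lines")
})

test_that("pixels with unusable white-dark range are masked, not clipped", {
  wl <- c(500, 600)
  raw <- hypercube(array(5, c(3, 3, 2)), wl, kind = "raw")
  white <- array(10, c(3, 3, 2))
  white[1, 1, ] <- 0    # dead pixel: white == dark
  dark <- array(0, c(3, 3, 2))
  r <- calibrate_reflectance(raw, white, dark)
  expect_false(r$mask[1, 1])
  expect_true(all(r$mask[-1, ]))
})

test_that("ROI segmentation recovers the generator's mask", {
  wl <- default_wavelength_grid()
  s <- 0.2 + 0.5 * seq(0, 1, length.out = 256)
  cb <- simulate_cube(s, c(24, 24), sim_config(), wl, seed = 5)
  refl <- calibrate_reflectance(cb$raw, cb$white, cb$dark)
  roi <- segment_roi(refl)
  expect_identical(mean(roi == cb$mask), 1)  # frozen from this fixture
  expect_error(segment_roi(refl, threshold = 1.2), "threshold")
})

test_that("segmentation of a background-only cube warns and returns empty", {
  wl <- c(700, 800)
  cube <- hypercube(array(0.02, c(8, 8, 2)), wl, kind = "reflectance")
  expect_warning(m <- segment_roi(cube), "empty")
  expect_false(any(m))
})

test_that("mean_spectrum averages masked pixels per band", {
  wl <- c(500, 600)
  a <- array(0.7, c(2, 2, 2))
  cube <- hypercube(a, wl, kind = "reflectance")
  mask <- matrix(TRUE, 2, 2)
  expect_equal(mean_spectrum(cube, mask), c(0.7, 0.7))
  a2 <- a
  a2[1, 1, 1] <- 0.2
  a2[2, 1, 1] <- 0.4
  cube2 <- hypercube(a2, wl, kind = "reflectance")
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube2, mask2)[1], 0.3)
  expect_error(mean_spectrum(cube2, matrix(FALSE, 2, 2)), "mask")
})
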