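test_that("MLR recovers generating coefficients exactly on noiseless data", {
  withr::with_seed(12, {
    X <- matrix(runif(40 * 4), 40, 4)
    beta <- c(3, -2, 0.5, 1.25)
    y <- 7 + drop(X %*% beta)
  })
  wl <- c(450, 550, 650, 750)
  m <- fit_mlr(toy_spectra(X, wl), y, wl)
  expect_equal(m$intercept, 7, tolerance = 1e-9)
  expect_equal(unname(m$coefficients), beta, tolerance = 1e-8)
})

test_that("a constant response gives a constant model", {
  withr::with_seed(3, X <- matrix(runif(30 * 3), 30, 3))
  wl <- c(400, 500, 600)
  m <- fit_mlr(toy_spectra(X, wl), rep(4.2, 30), wl)
  expect_equal(m$intercept, 4.2, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), rep(0, 3), tolerance = 1e-10)
})

test_that("the 3-point single-predictor fit matches hand least squares", {
  tbl <- toy_spectra(matrix(c(0, 1, 2), 3, 1), 500)
  m <- fit_mlr(tbl, c(1, 3, 5), 500)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
})

test_that("rank-deficient and under-determined designs are rejected", {
  withr::with_seed(4, X <- matrix(runif(20 * 2), 20, 2))
  X3 <- cbind(X, X[, 1] + X[, 2])
  wl <- c(400, 500, 600)
  expect_error(fit_mlr(toy_spectra(X3, wl), rnorm(20), wl),
               "collinear")
  expect_error(fit_mlr(toy_spectra(X3[1:4, ], wl), rnorm(4), wl),
               "n > m \\+ 1")
})

test_that("OLS residuals are orthogonal to the design", {
  withr::with_seed(6, {
    X <- matrix(runif(50 * 5), 50, 5)
    y <- drop(X %*% runif(5)) + rnorm(50, 0, 0.3)
  })
  wl <- seq(400, 800, by = 100)
  tbl <- toy_spectra(X, wl)
  m <- fit_mlr(tbl, y, wl)
  resid <- y - predict(m, as_preprocessed(tbl, "raw"))
  expect_lt(max(abs(crossprod(cbind(1, X), resid))), 1e-8)
})

test_that("PLSR needs one component for rank-one structure", {
  withr::with_seed(7, {
    t_ <- runif(30)
    X <- outer(t_, runif(12))
    y <- 2 + 3 * t_
  })
  tbl <- toy_spectra(X, seq(400, 950, length.out = 12))
  m <- fit_plsr(tbl, y, max_lv = 5)
  expect_identical(m$lv, 1L)
  expect_lt(m$cv$rmsecv[1], 1e-8)
})

test_that("full-rank PLSR with all components reproduces OLS predictions", {
  withr::with_seed(8, {
    X <- matrix(rnorm(25 * 4), 25, 4)
    y <- drop(X %*% c(1, -2, 0.5, 3)) + rnorm(25, 0, 0.2)
  })
  wl <- c(410, 520, 630, 740)
  tbl <- toy_spectra(X, wl)
  fit <- kiwispec:::nipals_pls(X, y, 4)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  pls_pred <- drop(X %*% fit$coef[, 4]) + fit$intercept[4]
  ols_pred <- drop(cbind(1, X) %*% ols)
  expect_equal(pls_pred, ols_pred, tolerance = 1e-8)
})

test_that("PLSR coefficients are invariant to sample order", {
  sim <- tiny_sim(5, seed = 19)
  z <- snv_spectra(sim$spectra)
  y <- sim$reference$ssc
  m1 <- fit_plsr(z, y, max_lv = 5, n_folds = 4)
  perm <- withr::with_seed(3, sample(nrow(z)))
  # refit on permuted rows at the same latent-variable count: the final
  # model is fit on all samples, so coefficients must agree
  fit1 <- kiwispec:::nipals_pls(spectra_matrix(z), y, m1$lv)
  zp <- spectra_matrix(z)[perm, ]
  fit2 <- kiwispec:::nipals_pls(zp, y[perm], m1$lv)
  expect_equal(fit1$coef[, m1$lv], fit2$coef[, m1$lv], tolerance = 1e-8)
})

test_that("prediction evaluates the linear form and checks preprocessing", {
  m <- kiwispec:::new_chemo_model(
    family = "mlr", intercept = 1,
    coefficients = c("500" = 2), wavelengths = 500,
    index = "ssc", units = "°Brix")
  x <- as_preprocessed(toy_spectra(matrix(3, 1, 1), 500))
  expect_equal(unname(predict(m, x)), 7)
  expect_error(predict(m, toy_spectra(matrix(3, 1, 1), 500)),
               "preprocessing mismatch")
  x_far <- as_preprocessed(toy_spectra(matrix(3, 1, 1), 900))
  expect_error(predict(m, x_far), "no band within")
})

test_that("published models carry the printed term counts and wavelengths", {
  counts <- c(ssc = 32L, firmness = 18L, lstar = 26L, astar = 29L,
              bstar = 32L)
  for (idx in names(counts)) {
    m <- published_model(idx)
    expect_identical(length(m$coefficients), unname(counts[idx]))
    expect_identical(m$wavelengths, published_wavelengths(idx, "cars"))
    expect_identical(m$preprocessing, "snv-full-spectrum")
  }
  expect_identical(published_wavelengths("a*", "cars"),
                   published_model("a*")$wavelengths)
  expect_identical(published_wavelengths("firmness", "cars")[1:4],
                   c(397, 402, 421, 432))
})

test_that("published-model intercepts are returned at all-zero predictors", {
  for (case in list(list("firmness", 235.6), list("SSC", -142.2),
                    list("L*", 197.6), list("a*", 54.9),
                    list("b*", -29.1))) {
    m <- published_model(case[[1]])
    x <- as_preprocessed(toy_spectra(
      matrix(0, 1, length(m$wavelengths)), m$wavelengths))
    expect_equal(unname(predict(m, x)), case[[2]])
  }
})

test_that("unknown indices and methods are rejected", {
  expect_error(published_wavelengths("sweetness", "cars"), "unknown")
  expect_error(published_wavelengths("ssc", "pca"), "arg")
  expect_error(published_model("sweetness"), "unknown")
})

test_that("models serialize to JSON and back losslessly", {
  sim <- tiny_sim(4, seed = 9)
  z <- snv_spectra(sim$spectra)
  m <- fit_mlr(z, sim$reference$ssc,
               published_wavelengths("ssc", "spa"),
               index = "ssc", units = "°Brix")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_identical(back$family, m$family)
  expect_identical(back$preprocessing, m$preprocessing)
})

test_that("tidy and glance expose terms and metadata", {
  m <- published_model("firmness")
  td <- tidy(m)
  expect_identical(nrow(td), 19L)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(td$estimate[1], 235.6)
  gl <- glance(m)
  expect_identical(gl$n_terms, 18L)
  expect_identical(gl$units, "kg·cm⁻²")
})
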