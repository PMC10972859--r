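# Published CARS-MLR calibrations and feature-wavelength sets for "Guichang"
# kiwifruit, shipped as fixtures. These coefficients were estimated on the
# original (undeposited) fruit data, so predictions made with them on other
# data are demonstrative, not validated.

.kiwi_indices <- c("ssc", "firmness", "lstar", "astar", "bstar")

.kiwi_index_units <- c(
  ssc      = "°Brix",
  firmness = "kg·cm⁻²",
  lstar    = "L*",
  astar    = "a*",
  bstar    = "b*"
)

.published_wavelengths <- list(
  ssc = list(
    cars = c(393, 400, 407, 428, 430, 432, 439, 446, 453, 460, 600, 614,
             878, 883, 891, 899, 904, 907, 920, 922, 925, 938, 941, 946,
             948, 956, 959, 972, 988, 993, 996, 1012),
    spa  = c(428, 432, 439, 446, 458, 580, 614, 656, 1017, 1025)
  ),
  firmness = list(
    cars = c(397, 402, 421, 432, 556, 590, 626, 824, 889, 904, 946, 954,
             964, 972, 975, 985, 1009, 1012),
    spa  = c(393, 397, 400, 402, 404, 409, 411, 442)
  ),
  lstar = list(
    cars = c(400, 402, 404, 428, 522, 592, 595, 597, 626, 629, 631, 634,
             636, 639, 698, 715, 721, 814, 824, 928, 1006, 1009, 1017,
             1020, 1022, 1028),
    spa  = c(393, 400, 402, 407, 411, 484, 525, 573, 653, 696, 711, 907, 998)
  ),
  astar = list(
    cars = c(402, 423, 430, 435, 453, 458, 489, 597, 617, 624, 626, 666,
             683, 746, 789, 791, 794, 822, 827, 855, 904, 920, 956, 975,
             977, 983, 998, 1001, 1004),
    spa  = c(407, 458, 520, 556, 678, 706, 852, 876, 964)
  ),
  bstar = list(
    cars = c(411, 416, 418, 423, 430, 439, 449, 463, 520, 551, 553, 592,
             595, 597, 617, 619, 622, 624, 626, 646, 746, 768, 786, 804,
             806, 922, 951, 969, 988, 996, 1020, 1022),
    spa  = c(411, 421, 425, 449, 522, 549, 590, 619, 863, 870, 938, 964,
             1017, 1028)
  )
)

# CARS-MLR calibration coefficients; predictors are SNV-preprocessed
# reflectance values of the full 256-band spectrum taken at the named
# wavelengths, responses in physical units.
.published_models <- list(
  ssc = list(
    intercept = -142.2,
    coef = c(
      "393" = -62.4, "400" = 111.4, "407" = -75.9, "428" = 146.5,
      "430" = 75.9, "432" = -214.4, "439" = 179.3, "446" = -188.1,
      "453" = -192.8, "460" = 152.2, "600" = 42.4, "614" = -99.5,
      "878" = 57.8, "883" = 253.8, "891" = -230.9, "899" = -134.0,
      "904" = -64.9, "907" = -186.6, "920" = 169.5, "922" = -19.2,
      "925" = 307.6, "938" = -147.5, "941" = 227.0, "946" = -265.4,
      "948" = -205.0, "956" = 416.7, "959" = 21.7, "972" = -203.8,
      "988" = 96.1, "993" = -70.4, "996" = -18.7, "1012" = 21.2)
  ),
  firmness = list(
    intercept = 235.6,
    coef = c(
      "397" = 208.4, "402" = -197.2, "421" = -130.9, "432" = 235.9,
      "556" = 178.8, "590" = -234.1, "626" = 203.0, "824" = 51.2,
      "889" = -161.2, "904" = 131.2, "946" = 262.1, "954" = -362.4,
      "964" = -279.4, "972" = 345.4, "975" = 289.4, "985" = -236.1,
      "1009" = 290.5, "1012" = -301.8)
  ),
  lstar = list(
    intercept = 197.6,
    coef = c(
      "400" = -85.7, "402" = 108.5, "404" = 36.5, "428" = -274.5,
      "522" = -108.8, "592" = -254.2, "595" = -1215.1, "597" = 1922.1,
      "626" = -216.1, "629" = -262.9, "631" = 574.0, "634" = -2265.0,
      "636" = 2142.0, "639" = -620.6, "698" = 151.6, "715" = -171.4,
      "721" = -22.6, "814" = -143.8, "824" = -58.6, "928" = -190.2,
      "1006" = -39.5, "1009" = -95.0, "1017" = -31.1, "1020" = -273.1,
      "1022" = 184.8, "1028" = 137.5)
  ),
  astar = list(
    intercept = 54.9,
    coef = c(
      "402" = 40.7, "423" = -73.1, "430" = -79.7, "435" = 132.3,
      "453" = -48.0, "458" = 192.8, "489" = -114.3, "597" = -290.3,
      "617" = 626.3, "624" = -309.5, "626" = -3.2, "666" = 77.1,
      "683" = -71.6, "746" = 48.9, "789" = 145.6, "791" = -13.8,
      "794" = -293.5, "822" = -14.8, "827" = 245.2, "855" = -132.5,
      "904" = 187.8, "920" = -138.3, "956" = -83.0, "975" = 36.8,
      "977" = 92.8, "983" = -29.6, "998" = 81.8, "1001" = 115.9,
      "1004" = -214.9)
  ),
  bstar = list(
    intercept = -29.1,
    coef = c(
      "411" = 60.6, "416" = 90.9, "418" = 130.2, "423" = -10.0,
      "430" = -269.5, "439" = -195.0, "449" = 294.3, "463" = 61.7,
      "520" = -191.4, "551" = 249.1, "553" = -67.2, "592" = 697.0,
      "595" = 207.6, "597" = -1374.3, "617" = -1011.1, "619" = 857.1,
      "622" = 1120.6, "624" = 754.0, "626" = -1003.2, "646" = -150.5,
      "746" = 191.1, "768" = -424.8, "786" = 287.9, "804" = 590.7,
      "806" = -526.7, "922" = 135.2, "951" = -132.0, "969" = 220.8,
      "988" = -200.4, "996" = 124.1, "1020" = 83.2, "1022" = -90.0)
  )
)

#' Normalise a physicochemical index name
#'
#' Accepts the display forms used in the literature (`"SSC"`, `"L*"`,
#' `"a*"`, `"b*"`) as well as the package's canonical keys.
#'
#' @param index Index name.
#' @return One of `"ssc"`, `"firmness"`, `"lstar"`, `"astar"`, `"bstar"`.
#' @keywords internal
normalize_index <- function(index) {
  stopifnot(is.character(index), length(index) == 1L)
  key <- tolower(gsub("[*_[:space:]]", "", index))
  key <- switch(key, "l" = "lstar", "a" = "astar", "b" = "bstar",
                "lstar" = "lstar", "astar" = "astar", "bstar" = "bstar",
                "ssc" = "ssc", "firmness" = "firmness", key)
  if (!key %in% .kiwi_indices) {
    stop("unknown physicochemical index: '", index,
         "' (expected one of SSC, firmness, L*, a*, b*)", call. = FALSE)
  }
  key
}

#' Published feature-wavelength sets
#'
#' Returns the feature wavelengths (nm) reported for a given
#' physicochemical index and selection method. Counts per index are
#' 32/18/26/29/32 for CARS and 10/8/13/9/14 for SPA (SSC, firmness,
#' L*, a*, b*).
#'
#' @param index Index name (`"SSC"`, `"firmness"`, `"L*"`, `"a*"`, `"b*"`).
#' @param method `"cars"` or `"spa"`.
#' @return Numeric vector of wavelengths in nm.
#' @export
#' @examples
#' published_wavelengths("firmness", "cars")
published_wavelengths <- function(index, method = c("cars", "spa")) {
  key <- normalize_index(index)
  method <- match.arg(tolower(method), c("cars", "spa"))
  .published_wavelengths[[key]][[method]]
}

#' Published CARS-MLR calibration models
#'
#' Loads one of the five published CARS-MLR calibrations as a
#' [`chemo_model`][fit_mlr] object. Predictors are SNV values of the full
#' 256-band spectrum at the model's feature wavelengths; coefficients are
#' stored to their printed precision, so predictions are approximate to
#' that precision. The coefficients were fitted to the original fruit
#' data, which is not distributed with this package: applying them to
#' other (e.g. synthetic) spectra demonstrates the mechanics only.
#'
#' @inheritParams published_wavelengths
#' @param grid Wavelength grid the model will be bound to; every model
#'   wavelength must be resolvable on it (see `tol`).
#' @param tol Matching tolerance in nm for binding model wavelengths to
#'   grid bands.
#' @return A `chemo_model` object (family `"mlr"`).
#' @export
#' @examples
#' m <- published_model("SSC")
#' glance(m)
published_model <- function(index, grid = default_wavelength_grid(), tol = 1) {
  key <- normalize_index(index)
  fix <- .published_models[[key]]
  wl <- as.numeric(names(fix$coef))
  # binding validates that each published wavelength exists on the grid
  invisible(vapply(wl, nearest_band, integer(1), grid = grid, tol = tol))
  new_chemo_model(
    family = "mlr",
    intercept = fix$intercept,
    coefficients = stats::setNames(unname(fix$coef), format_wl(wl)),
    wavelengths = wl,
    index = key,
    units = .kiwi_index_units[[key]],
    lv = NA_integer_,
    source = "published"
  )
}

#' Units of the five physicochemical indices
#'
#' @return Named character vector keyed by canonical index name.
#' @export
index_units <- function() .kiwi_index_units
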