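Package: kiwispec
Title: Hyperspectral Chemometrics for Fruit Quality Prediction and Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for predicting physicochemical
    quality indices of fruit (soluble solid content, firmness, and CIELAB
    colour) from visible/near-infrared hyperspectral images. Provides
    dark/white reflectance calibration and ENVI-style cube input/output,
    standard normal variate (SNV) preprocessing, SPXY joint x-y sample-set
    partitioning, CARS and SPA feature-wavelength selection, PLSR (NIPALS)
    and MLR calibration with RPD-based evaluation, pixel-wise prediction
    maps with pseudo-colour rendering, and a synthetic-hypercube generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
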