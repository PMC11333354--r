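Package: dendrosap
Title: Soil-Moisture Thresholds for Tree Water Deficit and Sap Flow from
    Dendrometer and Thermal-Dissipation Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes high-resolution stem-radius (point dendrometer) and
    Granier-type thermal-dissipation records together with soil-moisture and
    meteorological series into drought-response statistics for individual
    trees and sites.  Implements the zero-growth tree water deficit (TWD),
    relative extractable water (REW), an exponential TWD-REW model whose
    fixed-slope tangent x-intercept defines the soil-moisture threshold k at
    which stem water deficits persist overnight, a segmented-regression
    alternative for k, and the linear decline of relative daily sap flow with
    REW below 0.5 (slope m) on high evaporative-demand days.  A mechanistic
    forward simulator generates complete synthetic site datasets with known
    k and m so that every stage of the pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
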