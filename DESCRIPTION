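Package: fourpop
Title: Four-Population Phytoplankton Absorption Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spectral phytoplankton absorption coefficient aph(lambda)
    as the sum of contributions from four phytoplankton groups (picophytoplankton,
    nanophytoplankton, dinoflagellates and diatoms), whose chlorophyll-a
    concentrations are obtained from total chlorophyll-a and sea-surface
    temperature through SST-dependent logistic partition functions. Provides
    calibration of the chlorophyll-specific absorption coefficients by bounded
    Levenberg-Marquardt least squares with bootstrap uncertainty, propagation of
    relative uncertainty into group-specific absorption (including log/linear
    lognormal transforms and pixel-wise raster application), a configurable
    case-1 forward reflectance model producing blue-to-green maximum band
    ratios, log10-space evaluation statistics, and synthetic observation and
    raster generators for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    ncdf4,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
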