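Package: commsync
Title: Multi-Scale Synchrony and Compensation Analysis for Community Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify synchrony versus compensatory dynamics in
    multispecies abundance time series at several temporal scales. Implements
    the Gross et al. year-to-year synchrony index (the mean correlation between
    each species and the rest of the community), surrogate-based null models
    that preserve autocorrelation while erasing cross-correlation (toroidal
    shift and the iterative amplitude-adjusted Fourier transform), a continuous
    Morlet wavelet transform and the time- and scale-resolved wavelet modulus
    ratio with pointwise surrogate significance, utilities to assemble monthly
    community matrices from long-format count records (seasonal averaging,
    guild aggregation, biomass conversion), and a forced Lotka-Volterra
    community simulator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
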