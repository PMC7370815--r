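Package: imagecontrast
Title: Average Image Contrast via the Autocorrelation Function at the Origin
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the average contrast of raster images as the
    autocorrelation function of the mean-centered luminance field evaluated at
    zero lag, estimated spectrally through the Wiener-Khinchin theorem
    (2D FFT), with a direct-summation oracle, radial autocorrelation profiles,
    chronological cohort timelines, and an exact Mann-Whitney U comparison of
    two exposure conditions. Includes a synthetic-image module (uniform,
    checkerboard, grating, Gaussian random field, two-tone patch fields) with
    analytically known contrast so the full pipeline is verifiable without
    proprietary images.
License: MIT
Encoding: UTF-8
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
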