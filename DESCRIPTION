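Package: ctiq
Title: Physico-Technical CT Image Quality Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the physico-technical evaluation of CT image quality:
    in-plane modulation transfer function (MTF) by the thin-wire point method
    and the circular-edge method, slice sensitivity profile (SSP) with FWHM,
    2D/1D noise power spectrum (subtracted and unsubtracted) with peak
    frequency and noise magnitude, ACR-style CT-number uniformity and accuracy
    checks, and low-contrast visibility scoring with dose matching. A digital
    phantom generator produces wire, rod-edge, uniform-noise, thin-foil,
    low-contrast and HU-insert images with analytic ground truth, so every
    metric is verifiable by parameter recovery without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
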