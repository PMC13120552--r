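Package: tomoBench
Title: Standardized Images and Diagnostic Metrics for Emission-Tomography
    Reconstruction Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained evaluation framework for single-photon emission
    tomography (SPECT) image reconstruction. Provides a modified Shepp-Logan
    software phantom with two background variants, an analytic ideal-collimator
    attenuated parallel-beam projector with Poisson counting noise, ART and
    MLEM iterative reconstructors with chi-square stationarity stopping, and a
    multi-domain diagnostic suite: global scalar metrics (chi-square, NMSE,
    PSNR, CC, SSIM, CNR), difference and chi-square maps, the Structure and
    Contrast Index (SCI) of residual maps, intensity (gray-value) histogram
    comparison, region-of-interest localized metrics, and jackknife
    uncertainties. Reconstruction methods are benchmarked against standardized
    Source, Detector, Ideal and Realistic reference images generated entirely
    in software.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
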