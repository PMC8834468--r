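Package: mwpls
Title: Moving-Window PLS Wavelength Selection and NIR Calibration for
    Fermentation Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Wavelength-selection and calibration toolkit for near-infrared
    (NIR) process monitoring. Implements PLS-1 regression with leave-one-out
    cross-validation, moving-window PLS regression (MWPLSR) residue lines,
    searching-combination moving-window PLS (SCMWPLS) interval optimization,
    Savitzky-Golay second-derivative pretreatment applied per contiguous
    spectral segment, and ISO 12099-style validation statistics (SEP, bias,
    RPD, bias and unexplained-error confidence limits). Includes a synthetic
    fermentation-NIR generator (Beer-Lambert Gaussian band mixtures with
    baseline, scatter, noise and detector saturation) emulating a multi-batch
    fruit-wine fermentation study design, plus readers and writers for a
    JCAMP-DX subset and comma-separated spectra tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
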