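Package: kpdrgp
Title: Robust and Kernel Partial Least Squares Calibration with Leverage Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate calibration tools for near-infrared style spectral
    data built around partial least squares (PLS1) regression and its robust
    and kernelized extensions. Implements iteratively reweighted partial
    robust M- and MM-regression (PRM, PRMM), one-step GM6 estimation with
    minimum volume ellipsoid (MVE) leverage weights, the diagnostic robust
    generalized potential (DRGP) procedure for multiple high-leverage point
    detection with its put-back rule, Gaussian-kernel PLS in a reproducing
    kernel Hilbert space, and the kernel partial diagnostic robust potential
    (KPDRGP) method that combines kernel PLS with DRGP screening of the
    kernel score space. Includes simulation generators for a contaminated
    sine calibration study and for NIR-like overlapping-peak spectra, and
    standard chemometric evaluation metrics (RMSE, R2, RPD, bias, SEP).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
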