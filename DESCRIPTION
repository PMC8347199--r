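Package: ramanclass
Title: Raman Micro-Spectroscopy Preprocessing and PLS-DA Tissue Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometric pipeline for hyperspectral Raman maps of tissue:
    a synthetic-spectrum generator with a curated band library (glycogen,
    collagen, lipid and cyanide markers with class-dependent amplitudes),
    two-stage fluorescence baseline correction (iterative modified polynomial
    fitting followed by penalized asymmetric least squares on a banded
    solver), spectral region selection and unit-area normalization, duplex
    representative train/test splitting, PLS-DA classification built on a
    NIPALS PLS1 core with 10-fold cross-validated latent-variable selection,
    VIP-score discriminant-region calling, and band-level analytics such as
    the 1655/1444 lipid-saturation intensity ratio and silent-zone band
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    data.table,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
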