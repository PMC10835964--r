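Package: leafnirs
Title: NIRS Calibration of Leaf Nitrogen and Phosphorus from Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calibration workflow for predicting leaf nitrogen and phosphorus
    content from near-infrared reflectance spectra (350-2500 nm) of fresh,
    pressed-dried, conservation-treated, and re-scanned herbarium leaf
    material. Provides replicate averaging and detector splice correction,
    deterministic Kennard-Stone calibration/validation splitting, a NIPALS
    partial least squares (PLS1) engine, randomized spectral-region search
    around the PLSR core with natural-log response transformation and
    F-statistic outlier screening, rank-based group comparison statistics
    (Kruskal-Wallis, Dunn's test, Pearson correlation), and a synthetic
    spectra generator that emulates a factorial fertilization experiment, a
    herbarium conservation-treatment experiment, and a storage re-scan
    experiment so the whole analysis runs and validates without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
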