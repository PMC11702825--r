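Package: octez
Title: Outer-Retina Ellipsoid-Zone Segmentation and Biomarkers for SD-OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of spectral-domain optical coherence
    tomography (SD-OCT) B-scans of the outer retina: synthetic layered-retina
    phantoms with known ground truth, a four-level U-Net for five-class outer
    retinal layer segmentation trained with a combined Dice and weighted
    cross-entropy loss, per-A-scan intensity-profile biomarkers of the
    ellipsoid zone (weighted peak distances, thickness, relative intensity,
    and granularity after total-variation denoising), en-face ellipsoid-zone
    area and width mapping over an ETDRS region of interest, and
    normality-routed two-group statistics with Pearson correlation screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
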