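Package: spheroidscreen
Title: High-Content and High-Throughput Drug-Response Analysis of Spheroid
    Arrays in Inverted Colloidal Crystal Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening drug responses of multicellular spheroids
    grown in hexagonal-close-packed (HCP) inverted colloidal crystal hydrogel
    scaffolds. Implements the elastic-microgel contact-mechanics model that
    predicts interconnecting channel diameters from the compressive modulus,
    circle-in-circle and HCP packing capacity calculations, a synthetic
    generator for three-channel fluorescence volumes and plate-reader
    well-scans with full ground truth, an automated high-content imaging
    pipeline (void detection, spheroid segmentation, per-voxel viability,
    circle maps), a high-throughput plate-reader path with the voxel-to-pixel
    ratio correction and Gaussian histogram fitting, Hill dose-response
    fitting with IC50 extraction, ROC/AUC group separation, and stain
    separation with two-channel Pearson correlation for histology sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
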