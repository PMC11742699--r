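Package: plaquelipids
Title: Lipid Unsaturation Profiling of Amyloid Plaques from Infrared
    Imaging and Shotgun Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A label-free workflow for quantifying lipid unsaturation in
    amyloid-beta plaques of post-mortem brain tissue. Provides quality
    filtering and extended multiplicative signal correction (EMSC) of
    infrared hyperspectral pixel spectra and per-pixel band-ratio
    unsaturation maps (A3012/A1738); affine and Helmert point-pair
    registration with Otsu-based plaque core/corona/ring masks and region
    mean spectra; tile-based whole-slide plaque scoring with max-value
    reassembly, a morphological refinement cascade, and export of laser-
    microdissection-ready polygons in stage coordinates; and a species-level
    lipidomics pipeline (shorthand-name parsing, lysolipid exclusion, molar
    normalization, double-bond and acyl-chain-length composition profiles,
    paired group contrasts with Welch tests, standardized-SVD PCA, linear
    SVM separation, and species correlation matrices). Calibrated synthetic
    generators for IR scenes and lipidome cohorts make every stage testable
    without access to human tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
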