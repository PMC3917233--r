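Package: quanthisto
Title: Automated Quantitative Histology of Radial Plant Organ Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation and quantitative analysis of transverse sections of
    radially organized plant organs such as the Arabidopsis hypocotyl during
    secondary growth. Provides tiled-image stitching, adaptive binarization and
    watershed segmentation of cell walls, per-cell morphometric and positional
    descriptors (including the incline angle of the cell major axis relative to
    the section radius), supervised cell-type classification with greedy feature
    selection and support-vector machines, mask-based quality control,
    section-level phenoprints with correlation-matrix principal component
    analysis, incline morphodynamics (Hartigans' dip test for bimodality, lowess
    radial trends), and Bayesian estimation of the arc period between phloem
    poles. A built-in synthetic-section generator makes every stage testable
    without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    MASS,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
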