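Package: spatialtme
Title: Spatial Immune Architecture Analysis for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compartment-resolved spatial single-cell analysis of
    tumour microenvironments imaged at micrometre resolution. Provides
    phenotyped cell-table and label-mask containers, spatial neighbour graphs
    (k-nearest-neighbour within a radius, and expansion-contact), unsupervised
    immune-neighbourhood detection, permutation-based cell-cell
    interaction/avoidance testing, compartment densities, a three-class
    spatial immunotype classifier (depleted, compartmentalised, enriched)
    with patient-level consensus and highest-immunotype aggregation,
    survival association (Kaplan-Meier, log-rank and log-rank trend tests,
    horizon ROC), and a synthetic tissue simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    survival,
    pROC
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
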