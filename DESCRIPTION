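Package: lotusmsi
Title: Annotation, Segmentation and Semi-Quantification of MALDI Mass
    Spectrometry Imaging Data from Seed Tissue
Version: 0.1.0
Authors@R:
    person("MSI", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for matrix-assisted laser
    desorption/ionization mass spectrometry imaging (MALDI-MSI)
    metabolomics of plant seed sections: reading and writing imzML/ibd,
    root-mean-square spectrum normalization, mean-spectrum peak picking,
    adduct-aware accurate-mass annotation against a compound library with
    blank-control and peak-shape filtering, k-means spatial segmentation
    of ion images, and per-tissue semi-quantitative metabolite tables.
    Ships a synthetic seed phantom generator with ground-truth manifests
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
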