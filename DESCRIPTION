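Package: endemapr
Title: Geostatistical Biogeography of Species Occurrences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-scale biogeographic analysis of species
    occurrence records: record cleaning, point- and kernel-density surfaces,
    species-richness tessellation, the corrected Habitat Specificity index
    over landscape patches (ecoregions), raster band correlation, bioclimatic
    profile clustering (Euclidean distance, WPGMA), support-vector-machine
    detection of climatic niche overlap, and Geographical Interpolation of
    Endemism (GIE) with consensus maps of areas of endemism. Includes a
    synthetic-landscape generator with planted spatial structure so every
    pipeline stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
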