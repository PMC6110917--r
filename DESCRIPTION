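Package: soilscape
Title: Multi-Scale Analysis of Edaphic Gradients and Soil Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for studying how soil pH and electrical
    conductivity gradients structure bacterial community diversity and
    composition across nested spatial scales (region, lake basin, and
    patterned-ground polygon transects). Provides a synthetic-landscape
    generator emulating a 3-basin x 8-polygon x 5-position sampling design,
    rarefaction and alpha/beta diversity, permutation matrix statistics
    (Mantel, partial Mantel, Mantel correlogram, ANOSIM, PERMANOVA with
    sequential partitioning), canonical correspondence analysis, and a
    sliding-window LMG relative-importance model of species richness along
    edaphic gradients with fixed-width bin normalization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
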