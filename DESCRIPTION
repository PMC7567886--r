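Package: histoscape
Title: Landscape Ecology and Spatial Point-Pattern Analysis of Classified
    Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Treats classified (label-map) histology images as categorical
    landscapes and quantifies tissue microarchitecture with the toolkit of
    landscape ecology and spatial statistics: FRAGSTATS-style patch, class
    and landscape metrics; information-theoretic landscape complexity
    measures; edge-corrected spatial point-pattern summary functions
    (Ripley's K and L, empty-space F, nearest-neighbour G, and J) with
    Monte-Carlo envelopes for complete spatial randomness and a studentized
    permutation test for grouped point patterns; hexagon-paradigm hepatic
    lobule size estimation from portal and central-vein annotations;
    pericentral scar-axis analysis of myofibroblast point sets; and a
    landscape-metric machine-learning pipeline (feature filtering, random
    forest classification, variable importance, k-means case clustering).
    Synthetic generators for clumpy rasters, clustered and regular point
    processes, jittered lobular lattices and bipolar scar fields make every
    component testable without any image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    randomForest,
    stats,
    survival,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
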