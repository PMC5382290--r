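Package: ccmigrate
Title: Quantitative 3D Analysis of Collectively Migrating Cell Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments, tracks and quantifies every nucleus and cell of a
    collectively migrating cell cluster (such as the Drosophila border cell
    cluster) in 4D two-channel fluorescence time-lapse stacks. Nuclei are
    segmented per frame with an intensity-weighted Gaussian mixture model,
    associated across frames by global assignment of a tracking-confidence
    matrix, and cell bodies are recovered by marker-controlled watershed on an
    oriented-filter enhanced membrane channel under a cluster-volume
    constraint. Downstream statistics include group polarization and angular
    momentum order parameters with a running/rotating mode classifier,
    polar-axis dynamics, neighbour-exchange detection from temporal changes of
    the pairwise distance matrix, morphological-opening protrusion detection,
    and signed cell-surface deformation fields with their summary energies.
    A seeded synthetic-movie generator provides ground-truthed benchmarks for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    EBImage,
    optparse
Config/testthat/edition: 3
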