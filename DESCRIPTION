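Package: minfluxpairs
Title: MINFLUX Localization Filtering, Trace Centers, and Receptor Pair Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing pipeline for 2D MINFLUX single-molecule
    localization data: quality filtering on emission rate (efo) and center
    frequency ratio (cfr), reduction of emission traces to trace centers by
    per-trace DBSCAN, detection of isolated fluorophore pairs and small
    clusters, nearest-neighbor and Ripley K/L/H point-pattern statistics,
    and a synthetic-data generator with ground truth for validating every
    stage, including the Rice-distribution bias that localization precision
    imposes on measured pair separations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
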