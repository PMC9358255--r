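Package: DFNCluster
Title: Two-Step Clustering of Dynamic Functional Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates recurring whole-brain connectivity states from
    component time courses. Computes tapered sliding-window Pearson
    correlation (dFNC) tensors, clusters them into states either by a
    conventional single-pass k-means over all pooled windows or by a
    memory-frugal two-step procedure (per-batch k-means sweeps over
    disjoint subject subsamples followed by clustering of the aggregated
    centroids), selects the model order by an elbow criterion, extracts
    per-subject state vectors, occupancy rates and transition counts, and
    quantifies clustering quality via a centroid distance ratio. Includes
    a synthetic-data generator with planted, time-switching covariance
    states so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'windowing.R'
    'kmeans.R'
    'pipeline.R'
    'features.R'
    'quality.R'
    'io.R'
    'cli.R'
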