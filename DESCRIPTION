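Package: taskFC
Title: Task-Based Functional Connectivity Metrics and Age-Group Inference
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for analysing age effects on task-based functional
    connectivity from region-of-interest (ROI) fMRI time series. Implements a
    Power-style 264-node parcellation model with network assignments and a
    20 mm centre-proximity exclusion, per-domain task regression and Pearson
    correlation matrices, positive/negative within- and between-network
    correlation summaries, system segregation for sensorimotor and association
    systems, proportionally thresholded weighted graph metrics (global
    efficiency and Louvain modularity), repeated-measures factorial MANCOVA
    with a motion-scrubbing covariate, Bonferroni-corrected follow-up
    contrasts, and brain-behaviour partial correlations. A synthetic-cohort
    generator with a planted network factor model provides fully reproducible
    inputs emulating a four-age-group, four-task-domain study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'taskFC-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'parcellation.R'
    'simulate.R'
    'connectivity.R'
    'metrics.R'
    'mancova.R'
    'stats.R'
    'pipeline.R'
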