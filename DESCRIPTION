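Package: missionTrends
Title: Time-Resolved Biomarker Trend Classification for Long-Duration Mission Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spectral trend analysis for short, unevenly sampled biomarker
    time series collected on a common mission time grid. Measurements are
    binned onto an 8-point grid spanning pre-flight to two months
    post-return, baseline-differenced and Euclidean-normalized, then
    classified into lag, spike-maximum and spike-minimum trend classes via
    Lomb-Scargle periodograms, periodogram-inversion autocorrelations and
    bootstrap null quantiles. Classified series are organised by two-level
    agglomerative clustering with silhouette-selected cluster counts,
    summarised per group as natural visibility graphs with temporal
    communities, and compared across subjects through a periodogram-distance
    similarity network with consensus community detection. A seeded
    synthetic-cohort generator with planted trend archetypes provides a
    recoverable ground truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), S4Vectors, SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: TimeCourse, Clustering, Network, Classification
RoxygenNote: 7.3.3
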