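Package: fosnet
Title: Brain-Wide c-fos Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for immediate-early-gene (c-fos) functional connectivity
    analysis across brain regions. Aggregates per-section bilateral cell
    counts into animal-by-region tables, screens regions with two-way
    (sex by training) ANOVA and planned Fisher's LSD contrasts, builds
    per-group interregional Pearson correlation matrices with exact
    small-sample p-values, thresholds them into binary functional networks,
    computes graph-theoretic measures (degree, betweenness, transitivity,
    assortativity, characteristic path length, small-worldness) and Markov
    clustering with modularity-based inflation selection, validates
    structure against degree-preserving rewired null ensembles, and
    identifies hub regions with robustness ranking across pruning
    thresholds. Includes a seeded synthetic cohort generator with planted
    covariance blocks and bridging hubs for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    MASS,
    car,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
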