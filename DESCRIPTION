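Package: pvstopo
Title: Topological Relationships Between Perivascular Spaces and White
    Matter Hyperintensities on Longitudinal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial (topological) relationships between
    MRI-visible perivascular spaces (PVS) and deep white matter
    hyperintensity (WMH) clusters across longitudinal imaging waves.
    Provides multiscale 3-D Frangi vesselness filtering and length-based
    filtering for PVS segmentation on T2-weighted images, statistical
    intensity thresholding with template-prior refinement for WMH
    segmentation on FLAIR, deep versus periventricular cluster
    classification, automated close/not-close adjacency classification of
    deep WMH clusters against baseline PVS, longitudinal cluster matching
    with four-way change labelling (increase around, increase close,
    increase not close, no increase), and the cohort-level statistics:
    count/percentage tables by lobar region, a random-intercept logistic
    model of cluster-count change, paired density comparisons, univariate
    R-squared burden analysis, and mask-agreement metrics (Dice,
    Bland-Altman, ICC).  A seeded synthetic-scene generator produces
    ground-truth-annotated longitudinal T2/FLAIR volume pairs so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
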