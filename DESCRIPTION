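Package: cstmove
Title: Community-State Typing and Longitudinal Cluster-Movement Analysis for
    Nasal Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for community-state-type (CST) analysis of longitudinal
    16S amplicon cohorts sampled around influenza-like illness (ILI)
    episodes: feature-table input/output and sample-level quality filters
    (16S qPCR load and minimum read depth), alpha diversity, rarefaction,
    Bray-Curtis and Aitchison (CLR) beta diversity, principal coordinate
    analysis, silhouette-guided complete-linkage clustering with
    dominant-taxon cluster labelling, permutation-based community statistics
    (PERMANOVA, ANOSIM, PERMDISP) with exhaustive enumeration for small
    designs, metadata screening and association testing, and a four-category
    classification of per-subject cluster movement across pre-season, ILI
    and post-season timepoints. Includes a Dirichlet-multinomial cohort
    simulator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    car,
    ape,
    withr
Config/testthat/edition: 3
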