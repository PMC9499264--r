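Package: rhizorank
Title: Rank-Based Integrative Evaluation of Biofertilizer Greenhouse Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the integrative evaluation of plant biofertilizer
    trials that combine physiological growth traits, rhizosphere community
    profiles and RT-qPCR gene expression. Provides per-treatment trait
    summaries with Kruskal-Wallis/Dunn group comparisons and compact letter
    displays, alpha-diversity indices (Shannon, Chao-1) and taxonomic
    relative-abundance profiles from OTU count tables, relative
    quantification of gene expression by the 2^-ddCt method with
    differential-expression classification, correlation-matrix PCA of
    treatment-by-trait matrices, and a rank-based evaluation matrix that
    merges all data layers into a single per-treatment score using a
    maximum-tie ranking rule. A Dirichlet-multinomial community simulator,
    a truncated-normal trait simulator and a Ct-level qPCR simulator
    generate complete synthetic studies with the same statistical structure,
    so every stage of the pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
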