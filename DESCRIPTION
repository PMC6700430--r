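Package: coatrophy
Title: Consensus Co-Atrophy Network Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds signed weighted co-atrophy networks from regional brain
    morphometry (FreeSurfer-style cortical thickness and ICV-scaled volumes),
    normalized as robust Z scores against a cognitively normal reference
    cohort. Detects consensus modules preserved between a baseline and a
    longitudinally subtracted dataset via topological overlap, summarizes
    each module by its eigengene (first principal component), and correlates
    module eigengenes with clinical progression traits such as conversion to
    dementia and cognitive decline speed. Includes a seeded synthetic-cohort
    generator with planted co-atrophy modules for validation, per-feature
    univariate statistics (Spearman correlations with FDR control, ROC-AUC
    and R-squared variable importance), and a one-call pipeline driven by a
    YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mclust,
    ape,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
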