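Package: gutcog
Title: Gut Microbiome, Acylated Ghrelin and Cognition Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable, tested pipeline for mixed-method gut-brain-axis
    cohort studies relating the fecal microbiome, acylated ghrelin and
    cognitive status. Provides ghrelin-derived indices (AG/UAG ratio and
    the age-adjusted ghrelin ratio), alpha/beta diversity with PERMANOVA
    and SIMPER decomposition, SparCC compositional correlation inference
    with co-occurrence network construction, Louvain communities and
    centrality-difference keystone detection, Mantel and per-species
    regression screens, ROC classification, a multilayer-perceptron
    dementia classifier with permutation feature contributions, and a
    two-latent-variable structural model with factor-score prediction.
    Includes a synthetic-cohort generator with planted compositional
    correlations, differential taxa and latent-factor structure so every
    stage can be exercised and validated without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
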