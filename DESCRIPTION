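Package: coordshift
Title: Age-Related Gains and Losses of Gene-Expression Coordination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects age-related changes in gene-expression coordination.
    A sparse linear gene-gene regulatory model (L1-regularised regression
    with stability selection) trained on reference data is used to
    reconstruct each gene's expression from its regulatory neighbours.
    Per-age-group predictability (Spearman correlation between observed
    and reconstructed expression) is regressed on age, calibrated against
    a degree-preserving target-swap network null and an age-permutation
    null, and significant changes are decomposed into expression-level and
    variance drivers and into within- versus between-module correlation
    changes. Includes a synthetic-data generator with planted coordination
    changes, count preprocessing (filtering, median-of-ratios
    normalisation, covariate residualisation, balanced age groups),
    network post-processing and propagation, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    data.table,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
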