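Package: survomics
Title: Multi-Omic Feature Selection and Survival Model Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares the prognostic power of genomic data types (mRNA
    expression, microRNA expression, copy-number alteration, somatic
    mutation, and their merged metabase) for cancer survival prediction.
    Provides source-specific feature filters, three feature-selection
    algorithms over multivariate Cox proportional hazards models
    (constrained particle swarm optimization, network-guided forward
    selection over protein-interaction graphs, and penalized
    elastic-net/LASSO selection), an evaluation layer (Harrell's
    concordance index, median-split log-rank test, Cohen's kappa agreement
    of prognostic indices), and a synthetic multi-omic cohort generator
    with planted prognostic structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    limma
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
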