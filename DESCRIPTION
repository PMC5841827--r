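Package: rhizochron
Title: Successional Dynamics and Microbiota Age Models for Root-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking root-associated microbial communities over the
    host plant life cycle from 16S OTU count tables: per-mille normalization and
    prevalence filtering, Bray-Curtis ordination and PERMANOVA variance
    partitioning, beta-regression trends of taxon proportions across root
    compartments and plant age, sparse random-forest models that predict plant
    age or developmental stage from OTU abundances ("microbiota age"),
    early/late colonizer classification, overdispersed exact tests for
    site-skewed taxa, and between-site convergence statistics. Includes a
    Dirichlet-multinomial generator of synthetic successional communities with
    exported ground truth, so every stage of the pipeline is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    emmeans,
    jsonlite
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
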