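Package: modrep
Title: Cross-Cohort Replication of Co-Expression Gene Signatures in
    Purified Immune-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("modrep", "maintainers", email = "modrep@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering and replicating
    transcriptional gene signatures across two independent cohorts of
    purified immune-cell bulk RNA-seq: negative-binomial differential
    expression (Wald pairwise and multi-group likelihood-ratio tests),
    removal of one unwanted-variation factor from model residuals,
    unsigned Spearman co-expression networks with topological-overlap
    module detection, Fisher-exact cross-cohort module replication,
    hub-gene selection by normalized intramodular connectivity,
    preranked permutation gene-set enrichment split by direction, a
    composite five-gene interferon score from qPCR Ct values, and a
    cross-validated classifier that stratifies intermediate-phenotype
    donors by prediction confidence. Ships a two-cohort synthetic count
    generator with planted modules and ground truth for recovery tests.
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
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
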