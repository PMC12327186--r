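Package: CtStability
Title: Reference-Gene Stability Analysis for qPCR Ct Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting stable reference (normalizer) genes and
    miRNAs from qPCR cycle-threshold (Ct) tables. Implements four
    independent stability algorithms - the comparative delta-Ct method,
    geNorm stepwise M-value ranking with pairwise variation, a model-based
    intra-/intergroup variance decomposition in the NormFinder tradition,
    and BestKeeper descriptive statistics with the per-sample geometric-mean
    index - together with a RefFinder-style geometric-mean consensus over
    competition ranks. Includes a seeded synthetic Ct generator with known
    ground truth for benchmarking, replicate handling and validation for Ct
    tables built on SummarizedExperiment, and cohort-definition helpers for
    bovine semen quality studies (sperm morphology defect aggregation and
    approval classification, CASA kinematic ratios, quartile-based motility
    grouping). Ships a worked bovine semen candidate-miRNA panel and the
    per-method stability tier fixture for both semen-quality conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: qPCR, GeneExpression, Normalization, Software
RoxygenNote: 7.3.3
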