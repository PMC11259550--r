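Package: epiage
Title: Age-Related DNA Methylation Analysis and Epigenetic Clocks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for blood DNA-methylation aging studies:
    age-related differential methylation position (DMP) discovery with
    cell-composition and BMI adjustment, genome-wide DMP density scans and
    sliding-window detection of methylation change-points across the lifespan,
    methylome-transcriptome integration (extreme-group probe-gene pairing with
    permutation p-values, motif enrichment, TF-methylation correlation),
    transformed-age elastic-net clock training with validation-MAE model
    selection, stepwise reduction to compact CpG panels, leave-one-out
    multi-modal surrogate clocks, and residual-based age-pace stratification
    with downstream phenotype, lifestyle and omics comparisons. A synthetic
    cohort generator with stored ground truth makes every stage testable
    without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    pracma,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, DifferentialMethylation, Aging,
    Regression
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
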