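Package: DominantPatterns
Title: Dominant Expression Pattern Discovery and Transcriptional Module
    Inference for Two-Genotype Developmental Microarray Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the transcriptome analysis of two-genotype,
    multi-stage developmental microarray experiments, built around a
    16-array (2 genotypes x 4 stages x 2 replicates) somatic-embryogenesis
    design. Provides RMA-style probe summarization (quantile normalization
    and median polish), Wilcoxon signed-rank detection calls with
    replicate-consensus presence, SAM-style permutation differential
    testing with fold-change gating, fuzzy K-means dominant-pattern
    discovery with correlation-based prototype merging and gene
    assignment, hypergeometric GO and promoter-motif over-representation,
    TF-motif-target transcriptional module graphs with Cytoscape export,
    2^-ddCt relative quantification, and a synthetic-data generator with
    planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    limma,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microarray, GeneExpression, Clustering, DifferentialExpression,
    GO, NetworkInference
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DominantPatterns-package.R'
    'utils.R'
    'detection.R'
    'differential.R'
    'enrichment.R'
    'io.R'
    'modules.R'
    'patterns.R'
    'pipeline.R'
    'preprocess.R'
    'qpcr.R'
    'synthetic.R'
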