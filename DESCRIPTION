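Package: striatax
Title: Interneuron Taxonomy Analysis for Single-Nucleus RNA-Seq of the Dorsal Striatum
Version: 0.1.0
Authors@R: person("striatax", "developers", email = "striatax@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for building an interneuron taxonomy from
    multi-donor, two-region single-nucleus RNA-seq of the human dorsal
    striatum (caudate nucleus and putamen). Provides bespoke nucleus-level
    quality control (multi-run doublet consensus, hard depth and
    mitochondrial filters, a polynomial gene~UMI outlier rule, Gaussian
    mixture marker-score thresholds, regional contamination removal),
    iterative marker-based classification with correlation-threshold class
    merging, centered-log-ratio compositional comparison of class abundances
    between regions, pseudobulk negative-binomial GLM likelihood-ratio
    differential expression with hypergeometric over-representation
    analysis, and single-latent-factor models of continuous within-subclass
    expression gradients. Includes a synthetic-data generator with planted
    ground truth that exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    irlba,
    FNN,
    jsonlite,
    yaml,
    ape,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
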