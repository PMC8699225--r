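Package: polyblup
Title: Weighted Genomic BLUP for Autopolyploid Crops
Version: 0.1.0
Authors@R:
    person("polyblup", "developers", email = "polyblup@example.org",
           role = c("aut", "cre"))
Description: Genomic selection toolkit for autotetraploid crops such as
    alfalfa and potato. Builds dosage-aware genomic relationship matrices
    (VanRaden, Yang, full-autotetraploid, and SNP-weighted variants),
    estimates variance components by restricted maximum likelihood through
    a single eigendecomposition, predicts genomic estimated breeding values
    (GEBVs) by GBLUP/RRBLUP, runs kinship-corrected single-marker
    association scans under the standard allele-dosage gene-action models
    (additive, diploidized, simplex/duplex dominant, general), converts
    association scores or machine-learning variable importances into marker
    weights for a weighted relationship matrix, and compares model
    configurations by repeated k-fold cross-validated Pearson accuracy.
    Includes a tetraploid genotype/phenotype simulator with controlled QTL
    architecture and heritability, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
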