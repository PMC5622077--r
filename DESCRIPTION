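Package: gwas2drug
Title: Drug Repurposing and Pathway Mapping from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to corroborate and generate drug-repurposing hypotheses from
    genome-wide association summary statistics. Implements gene-level
    association scoring from SNP p-values with linkage-disequilibrium-aware top
    and mean models, competitive gene-set regression with gene covariates, drug
    gene-set construction from drug-gene interaction tables with ATC class
    annotation, enrichment-curve AUC statistics for therapeutic drug classes
    with Wilcoxon-Mann-Whitney significance, kernel generative topographic
    pathway maps colored by kriging, and protein-protein interaction network
    metrics for target prioritization, together with a seeded synthetic-data
    generator so the whole workflow can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
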