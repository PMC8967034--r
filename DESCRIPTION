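Package: proteoscape
Title: Metaproteomic Landscapes of Microbial Communities
Version: 0.1.0
Authors@R:
    person("GutBac", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Downstream analysis of community metaproteomics: target-decoy FDR
    filtering and sample QC of peptide-spectrum match (PSM) tables, spectral
    allocation of unique and multi-mapped spectra to genomes with proteome-size
    and depth normalization, a Shannon-entropy host-phenotype-specificity score,
    sparCC-based protein co-expression networks with clique-seeded module
    extraction and guilt-by-association pathway suggestion, operon candidate
    inference from genomic adjacency with spectral-support filtering,
    six-frame-translation rescue of open reading frames missed by de novo gene
    predictors, and a COG/pathway annotation layer with parsimony pathway
    minimization. Includes a synthetic-community generator with full ground
    truth so every stage is testable without external mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
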