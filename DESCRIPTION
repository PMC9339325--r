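Package: chemrep
Title: Chemosensory Receptor Repertoire Dynamics in Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the expansion dynamics of chemosensory gene
    families (gustatory receptors in particular) in insect genomes:
    iterative homology-based annotation of tandem-duplicated gene
    clusters with rule-based curation (allele collapse at 90% identity,
    pseudogene and completeness calls, TYhhhhhQF motif screening),
    locus-overlap enrichment tests for transposable elements around gene
    clusters (flank-and-merge region construction, Fisher's exact test,
    FDR correction), duplication-loss reconciliation of gene trees with
    species trees (LCA parsimony, per-branch gains/losses, ancestral
    repertoire sizes), and a gated dN/dS selection screen built on
    Goldman-Yang codon models (M0, M8 vs M8a, branch-site model A with
    likelihood-ratio tests and q-values). Includes seed-deterministic
    synthetic-data generators (genomes with gene clusters and TE
    insertions, birth-death gene families, codon alignments) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, Matrix, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
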