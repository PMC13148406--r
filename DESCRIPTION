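Package: markerphylo
Title: Phylogenomic Species-Tree Inference from Single-Copy Marker Profile Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A checkpointed phylogenomic pipeline that identifies single-copy
    orthologous genes in annotated genomes by profile hidden Markov model
    search against a marker set (BUSCO-style), aligns the orthologs in profile
    match-state coordinates, trims alignments to parsimony-informative sites,
    ranks markers by treeness over relative composition variability, and
    infers a species tree by either quartet-based consensus across gene trees
    or supermatrix concatenation with nonparametric bootstrap and site
    concordance factors. Includes a deterministic simulator of marker gene
    families evolved along a known species tree for end-to-end validation,
    a HMMER3 text-format reader/writer, and benchmarking utilities
    (Robinson-Foulds distance, monophyly assessment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    digest,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
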