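Package: pbmnet
Title: Transcription Factor Target Discovery from Protein Binding
    Microarrays, Co-Expression and Promoter Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative workflow for identifying transcription factor
    (TF) target genes and assembling TF to functional-module regulatory
    networks. Protein binding microarray (PBM) probe intensities are
    converted into rank-based enrichment scores for gapped and ungapped
    k-mers, summarised into core words and position weight matrices, and
    clustered into DNA-binding specificity groups. High-scoring seed
    k-mers are scanned against promoters extracted under an
    upstream-neighbour truncation rule to give raw target sets, which are
    refined by a hypergeometric co-expression filter over expression
    compendia and by multi-species phylogenetic footprinting with an
    empirical resampling false discovery rate. The resulting tiers of
    evidence feed a regulatory network annotated with functional-module
    enrichments mapped to ten GO-slim categories. A seeded synthetic-data
    generator with planted ground truth makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
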