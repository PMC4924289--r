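Package: frbpipe
Title: Fuzzy Reciprocal Best-Hit Homology Assignment and Gene Gain/Loss
    Mapping Across Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for seed-based homologue surveys across draft genomes:
    fuzzy reciprocal best-hit (FRB) homology assignment from protein
    similarity searches, tiered reconciliation of newly predicted gene
    models against published annotations (minor/major refinement,
    split and merged model pathologies), rescue of missing genes from
    read-to-protein alignment depth profiles, assembly of best-evidence
    presence/absence matrices, Dollo parsimony gain/loss reconstruction
    on a species tree, and collapsing of poorly supported tree branches.
    Includes a deterministic local protein aligner front-end, strict
    readers/writers for FASTA, GFF3, 12-column tabular hit files and
    Newick, and a synthetic-genome generator with planted ground truth
    for end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
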