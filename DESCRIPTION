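Package: gudgar
Title: Discovery and Quantification of Oxidized-Sugar (gud/gar) Metabolism
    in Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for discovering and quantifying bacterial
    metabolism of the oxidized sugars glucarate and galactarate (the gud/gar
    pathway) across microbial genomes. Builds position-specific scoring
    models from seed alignments and scores proteomes by profile
    Smith-Waterman local alignment with empirically calibrated E-values;
    calls per-genome pathway presence through a configurable boolean pathway
    grammar; infers operons from gene coordinates and flags unannotated
    co-operonic genes as candidate pathway members; compares gene clusters
    by greedy homology matching; builds neighbor-joining gene trees,
    reconstructs ancestral states by Fitch parsimony, reports
    clade-diagnostic residues, and detects gene-tree/species-tree
    incongruence consistent with horizontal gene transfer; and profiles
    gene-catalog abundance in sequencing samples with counts-per-million
    normalization and Mann-Whitney group comparisons. A synthetic-data
    module generates species trees, protein families, annotated genomes
    with planted gene clusters, reads, and count matrices so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
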