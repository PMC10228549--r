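Package: magce
Title: Functional Classification of Metagenome-Assembled Genomes in
    Chain-Elongation Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies metagenome-assembled genomes (MAGs) into
    chain-elongation functional groups (Ferment to Intermediates,
    Intermediate Chain Elongators, Carbohydrate Chain Elongators,
    uninvolved) from translated homology detection of fermentation-pathway
    enzymes.  Provides a six-frame translated protein homology search with
    an exact affine-gap local aligner and Karlin-Altschul E-values,
    per-genome pathway-completeness profiling, Mash-style ANI genome
    dereplication with score-weighted representative selection,
    relative-abundance filtering, Bray-Curtis NMDS ordination and
    PerMANOVA, a rule-based and a trainable multiclass classifier for
    functional-group assignment, distance-based EtfB homolog function
    assignment, and a synthetic-data generator that emulates the
    statistical structure of chain-elongation bioreactor metagenomes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
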