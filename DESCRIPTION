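Package: kinevo
Title: Evolution of Protein-Kinase Substrate Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protein-kinase substrate specificity
    evolves across a kinase-domain phylogeny. Implements per-position
    divergence scoring between sister clades from ancestral sequence
    posteriors (S = RC - AC * p(AC)), cross-family switch aggregation with
    functional-category enrichment tests, position-weight-matrix comparison
    by Frobenius distance with a subsampling-derived specificity-divergence
    threshold, phosphorylation-motif discovery with a superset-conditioned
    binomial enrichment statistic and cross-species motif filtering,
    maximum-likelihood dating of kinase-unit origins under a two-state
    Markov model, and phylogenetic comparative statistics (independent
    contrasts, Blomberg's K, Pagel's lambda). Includes a full synthetic-data
    layer (simulated family alignments with implanted specificity switches,
    PWM-sampled target sites, motif-implanted phosphoproteomes, Markov and
    Brownian traits) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phytools,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
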