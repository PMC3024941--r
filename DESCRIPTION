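Package: picsord
Title: Ordination-Based Integer Recoding of Ambiguous Alignment Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recodes ambiguously aligned regions of a fixed multiple
    sequence alignment as ordered integer characters for partitioned
    phylogenetic analysis. Pairwise distances within each region are
    computed from sequence identities or from optimal global alignments
    under log-affine gap costs (including a zeta power-law / Kimura
    2-parameter model), ordinated by principal coordinates analysis
    retaining positive-eigenvalue axes only, and rescaled to small
    integer codes that are merged with the unambiguous DNA partition
    and written in RAxML and PAUP compatible formats. Also provides
    automatic delimitation of ambiguous regions from conserved 5-base
    flanks, a sequence evolution simulator with power-law indel
    lengths, and relative Robinson-Foulds tree comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
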