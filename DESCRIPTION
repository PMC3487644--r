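Package: mpmorph
Title: Maximum Parsimony Analysis of Morphological Character Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equal-weights maximum parsimony for discrete morphological
    character matrices with unordered (Fitch) characters, including
    polymorphic, missing and inapplicable cells.  Provides exact
    branch-and-bound and random-addition-plus-branch-swapping (NNI, SPR,
    TBR) tree searches, zero-minimum-length branch collapsing and
    topology deduplication, strict consensus, ensemble and per-character
    consistency and retention indices, ACCTRAN/DELTRAN character-state
    optimization with synapomorphy mapping, and a generator of synthetic
    matrices evolved on known trees with controlled homoplasy.  Ships the
    38-character, 20-taxon adult-morphology matrix for the tortoise
    beetle genus Stoiba (Coleoptera: Chrysomelidae: Cassidinae) and its
    outgroups as a packaged data set, together with a one-call
    reproduction of the full analysis (tree search, consensus, fit
    indices and clade supports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
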