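Package: StructKmer
Title: Alignment-Free Comparison of RNA Secondary Structures with
    Structural k-mers
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free similarity scoring, clustering and k-mer-space
    exploration for RNA secondary structures.  Dot-bracket structures are
    annotated into per-nucleotide structure arrays over the eight-letter
    alphabet {H, M, X, I, B, E, L, R} (hairpin, multiloop, external loop,
    internal loop, bulge, end, left- and right-handed stem).  Structures are
    compared by the cosine similarity of their structural k-mer count
    vectors, down-weighted by a relative length penalty, with an optional
    "fuzzy" mode that adds exp(-d) pseudo-counts for k-mers within a small
    edit distance d of observed k-mers.  The package also provides affinity
    propagation clustering of all-vs-all score matrices with evaluation
    against known subclass labels, an edit-distance network over the
    observed k-mer space, and a generator of synthetic pseudoknot-free
    structure families with planted labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
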