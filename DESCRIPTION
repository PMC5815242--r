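Package: hammingpairs
Title: Threshold Hamming-Distance Pairs, goeBURST Forests and Queries for
    Typing Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes all pairs of MLST/cgMLST/wgMLST allelic profiles (or
    other equal-length categorical sequences) within a Hamming distance
    threshold k in average-case linear time, by indexing the concatenated
    profiles with a suffix array, LCP array and range-minimum-query structure
    and filtering candidate pairs through a pigeonhole block partition.
    The truncated distance matrix feeds two use cases: goeBURST minimum
    spanning forests over the threshold graph (clonal complexes), and
    k-closest querying and classification of new profiles against an indexed
    database. Includes a seeded generator of uniform synthetic profiles with
    planted close pairs, and the admissibility bound on k under which the
    average-case guarantee holds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
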