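Package: msaframe
Title: A Unified Framework for Progressive Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements progressive multiple protein sequence alignment as a
    five-stage pipeline with interchangeable components: five pairwise
    similarity scorers (global affine-gap identity, shared tuples, longest
    common subsequence, k-mer counts, and pair-HMM posterior expected
    accuracy), four guide-tree builders (UPGMA-style averaging, two
    single-linkage variants, and Neighbor-Joining), an optional T-COFFEE-style
    consistency transformation of a residue-pair constraint library, Clustal
    W-style profile-profile alignment with sequence weighting and
    position-specific gap penalties, and tree-restricted iterative refinement
    maximizing the weighted sum-of-pairs objective. Includes benchmark scoring
    (Developer Score, alignment identity), a paired one-sided Wilcoxon
    signed-rank comparison harness for strategies, and a synthetic protein
    family generator with known reference alignments for controlled testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
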