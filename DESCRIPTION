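Package: kmergeo
Title: Alignment-Free k-mer Dissimilarities for Geographic Sourcing of
    Shotgun Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Background-adjusted alignment-free dissimilarity measures
    (d2*, d2s, CVTree, plus Manhattan, Euclidean and d2) between shotgun
    read sets, with Markov-chain null models for expected word counts;
    K-nearest-neighbor continent-of-origin classification with bootstrap
    reference-confidence and read-resampling NGS-confidence scores;
    permutation Wilcoxon-Mann-Whitney tests of intra- versus
    inter-continental dissimilarities, principal coordinate analysis and
    great-circle-distance correlation; and a synthetic three-continent
    population and shotgun-read simulator with substitution-error
    injection so the whole pipeline can be exercised without large
    sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
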