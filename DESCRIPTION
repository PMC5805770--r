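Package: readforest
Title: Reference-Free Lossless Compression of Fixed-Length Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free lossless compressor for multisets of fixed-length DNA
    sequencing reads. Reads are organised greedily into a minimum-total-weight
    "read forest" of cycle-rooted tries by suffix-prefix overlap matching with
    K-mer seeded, mismatch-tolerant extension and an optional strand-correction
    heuristic. The forest is serialised to a compact binary container (2-bit
    packed consensus streams, fixed-codebook Huffman differential offsets,
    Elias-gamma side streams) and decoded back bit-exactly. The package also
    provides an information-theoretic approximation of the entropy of a read
    collection (genome term via a universal compressor, Poisson sampling term,
    substitution-error term), a synthetic read simulator matching the model's
    assumptions, and brute-force oracles certifying the greedy construction's
    combinatorial optimality and the shortest-superstring bound.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
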