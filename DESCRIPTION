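Package: ampsort
Title: Reference-Free Sorting of Long Amplicon Reads into Species Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sorts noisy long-read amplicon sequences (e.g. Oxford Nanopore
    reads of barcoding loci) into gene groups and species groups without any
    reference database, using global edit-distance similarity with a length
    gate and reverse-complement rescue, best-match graph clustering, iterative
    threshold-relaxation assignment to evolving consensus sequences, and a
    star-alignment majority-vote consensus per species group. Includes an
    ONT-like read simulator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    igraph,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
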