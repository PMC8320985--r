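Package: eorscode
Title: Constrained DNA Storage Code Sets via Equilibrium Optimization and
    Random Search
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs sets of fixed-length DNA codewords for DNA data
    storage that jointly satisfy a minimum pairwise Hamming distance, an
    exact GC-content weight and a no-runlength (homopolymer-free)
    constraint.  Implements the EORS heuristic -- an equilibrium-optimizer
    population search over continuous concentration vectors followed by a
    random-search augmentation pass with a single-conflict swap rule --
    together with an exact branch-and-bound maximum-clique oracle on the
    compatibility graph of all valid codewords, a randomized-greedy
    baseline, coding-rate analytics, plain-text/FASTA input and output,
    and a command-line interface with a benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
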