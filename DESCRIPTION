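Package: mockmap
Title: Mock Metagenomic Communities, Reference Read Mapping, and Coverage
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A self-contained toolkit for benchmarking shotgun metagenomic
    community profiling against known truth. Builds and dereplicates
    strain-indexed reference genome databases using canonical k-mer
    containment, simulates mock communities of known composition (paired-end
    and fragment reads with substitution errors and per-read truth labels),
    screens reads for low-complexity sequence with a DUST-style mask,
    maps reads with a seed-and-extend aligner under explicit
    length-fraction and similarity filters, resolves multi-mapping reads
    under top-random, unique-only, topN and all-hits strategies, computes
    per-strain breadth and depth of coverage with detection cutoffs, rolls
    abundances up to species and genus level, and evaluates taxonomic
    resolution against the simulated ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
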