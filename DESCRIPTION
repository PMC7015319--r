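Package: ribosim
Title: Stochastic Whole-Cell Simulation of Prokaryotic mRNA Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of protein synthesis in a
    prokaryotic cell, in which thousands of codon-explicit mRNAs are translated
    by ribosomes that compete for finite pools of tRNAs, ternary complexes,
    initiation, elongation, termination and recycling factors. Event selection
    uses a binary tree over per-mRNA propensity sums, giving log2(N) cost per
    reaction. The package also builds synthetic transcriptomes whose codon bias
    is matched to tRNA abundances (and solves the inverse tRNA/codon-usage
    matching problem), scales molecular pools with ribosome content, and
    computes the standard observables of translational kinetics: peptide chain
    elongation rate, ribosome state fractions, free ternary-complex ratios,
    per-codon decoding times and stalling frequencies, and ribosome spacing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
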