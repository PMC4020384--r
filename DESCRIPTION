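Package: evosim
Title: Monte Carlo Simulation of Molecular Sequence Evolution Along
    Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates nucleotide, codon and amino-acid alignments along
    user-supplied or coalescent-simulated time-calibrated phylogenies
    under normalized continuous-time Markov chain substitution models
    (HKY, TN93, GTR, GY94, MG94, empirical amino-acid matrices and
    general, possibly sparse or non-reversible, discrete-state
    processes), discrete-gamma plus invariant-sites rate heterogeneity,
    strict and uncorrelated relaxed molecular clocks, multi-partition
    designs with per-partition trees and gap padding, and piecewise
    time-heterogeneous (epoch) substitution processes.  A
    pruning-based exact site-pattern probability engine provides an
    independent validation harness for simulator output, and a
    scripted epoch study explores sequence saturation under
    time-varying selective pressure.  Output in FASTA or NEXUS;
    genealogies for heterochronous samples are generated under
    constant-size or exponential-growth coalescent models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Matrix,
    Biostrings,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
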