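Package: rnaworld
Title: Agent-Based Replicase-Parasite Simulation of an RNA World
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Individual-based stochastic simulation of an RNA World population
    in continuous two-dimensional space. Every agent carries an explicit
    50-nucleotide RNA sequence from which its behaviour is derived: a folded
    fraction from maximum base-pairing secondary structure prediction, a
    replicase efficiency from an ungapped match to a 5' catalytic motif, and a
    decay rate from dinucleotide-specific phosphodiester hydrolysis. Agents
    diffuse by Brownian dynamics on a torus, form enzyme-template complexes,
    replicate with point mutations, decay with exponential waiting times, and
    are removed under local crowding. Includes scenario builders (ideal
    replicase pools, random pools, hydrolysis-table variants, parameter
    sweeps), trajectory statistics, survivor export to FASTA, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
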