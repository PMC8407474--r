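Package: stogrow
Title: Stochastic Single-Cell Growth Simulation with Bursty Gene
    Expression and Metabolic Division Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth and division of single bacterial cells in
    which burst-like transcription of biosynthetic operons drives
    Michaelis-Menten production of a set of limiting biomass precursor
    metabolites, and cell division fires when every metabolite pool meets a
    metabolic Adder or Sizer threshold.  Provides lineage-tree simulation
    with burn-in, generation-time analysis (log-GEV maximum-likelihood
    fits, distribution moments, population growth rate from sorted birth
    events, Monod curve fits), and metabolite-exchange scenarios: uptake,
    secretion, auxotrophy with flux redistribution, and a single-cell
    cross-feeder proxy with feasibility classification.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    e1071,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
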