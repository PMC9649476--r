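Package: sepsisBN
Title: Boolean Network Modelling of the TLR4-Mediated Inflammatory Response in Early Sepsis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logical (Boolean network) modelling of the innate immune response
    triggered by Toll-like receptor 4 during early Gram-negative sepsis.
    Ships a 42-node literature-derived network of immune cells, cytokines,
    complement and coagulation factors, together with a rule language that
    supports time-delay threshold terms, a stochastic asynchronous simulation
    engine with knock-out/over-expression clamps and fractional-activity
    (polymorphism) nodes, attractor readout as per-node percent activation,
    and screening pipelines for immune-cell sensitivity analysis and mono,
    pairwise and antibiotic-combination perturbation screens against four
    clinical surrogate endpoints (phagocytosis, membrane attack complex,
    thrombosis and angiopoietin-2). Small toy networks with exactly solvable
    Markov-chain behaviour are included for engine validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
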