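Package: evolvexga
Title: Model-Guided Design of Growth-Coupled Production Strategies for
    Adaptive Laboratory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Searches combinations of metabolic reaction knockouts and
    chemical-environment components that couple user-selected fluxes (for
    example a heterologous production pathway) to growth in a genome-scale
    metabolic model, so that the coupled fluxes become improvable by
    adaptive laboratory evolution.  Provides the EvolveX flux-coupling
    score (a two-stage mixed-integer linear program: minimal total nutrient
    uptake at fixed growth, then the worst-case sum of target flux
    couplings), a fixed-cardinality genetic algorithm over knockout and
    environment sets, search-space pruning by growth/production
    essentiality and blocked-reaction analysis, and a modified ROOM
    procedure that identifies native precursor, energy and redox reactions
    whose flux must increase for production.  Models are read from SBML
    Level 3 (fbc) or a simple tabular format; the constraint-based
    machinery (FBA, FVA, parsimonious FBA) is built on an internal
    bounded-variable simplex and branch-and-bound solver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
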