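Package: mimbl
Title: Stoichiometry-Representation-Independent Constraint-Based Metabolic Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constraint-based simulation of metabolic networks with objective
    functions cast in metabolite-turnover space. Implements flux balance
    analysis (FBA), linear and quadratic minimization of metabolic adjustment
    (lMoMA, qMoMA), normalized lMoMA, flux and turnover minimization, and the
    two-step Minimization of Metabolites Balance (MiMBl), whose predictions
    are invariant under rescaling of stoichiometric coefficients. Includes
    reaction and gene knockout simulation with gene-protein-reaction rules,
    flux variability analysis under objective locks, enumeration of
    alternative optima, genetic-interaction (epistasis) screening, metabolic
    network distance, scaling-sensitivity scans, SBML and tabular model
    input/output, and deterministic synthetic-model generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    igraph,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
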