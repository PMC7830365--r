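Package: aoqsar
Title: QSAR Consensus Modeling of Antioxidant Chain-Termination Rate Constants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the rate constant k7 for the reaction of antioxidants
    (substituted phenols, aminophenols, aromatic amines and uracils) with
    peroxyl radicals in liquid-phase chain oxidation. Implements QNA
    (Quantitative Neighbourhoods of Atoms) and MNA (Multilevel
    Neighbourhoods of Atoms) atomic descriptors together with
    whole-molecule descriptors (topological length, topological volume,
    lipophilicity, physicochemical counts), self-consistent regularized
    regression (SCR) with radial-basis-function interpolation (RBF-SCR),
    consensus ensembles of partial regressions with applicability-domain
    diagnostics, rank-ordered train/test splitting, leave-many-out
    cross-validation and a full external-validation metric suite (Q2F1,
    Q2F2, rm2, CCC, RMSEP, MAE). A kinetics module extracts fk7, the
    stoichiometric inhibition coefficient f, and k7 from inhibited
    oxidation measurements, and a synthetic-data module generates
    structure-linked activity data and simulated kinetic experiments for
    testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
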