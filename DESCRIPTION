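Package: mcf7qsar
Title: QSAR Modeling and Candidate Design for Dihydropteridone-Oxadiazole
    MCF-7 Inhibitors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Descriptor-based QSAR (quantitative structure-activity
    relationship) modeling of dihydropteridone derivatives bearing an
    oxadiazole moiety as inhibitors of MCF-7 breast-cancer cells. Ships the
    published 33-compound descriptor panel and 31-compound modeling table as
    validated fixtures, and provides multiple linear regression, second-order
    polynomial regression and a seeded 6-3-1 feed-forward neural network over
    the six model descriptors (stretch energy, torsion energy, melting point,
    rotatable-bond count, repulsion energy and hardness); leave-one-out
    cross-validation (Q2), the Golbraikh-Tropsha external-validation battery,
    hat-matrix leverage applicability-domain analysis (Williams plot),
    activity prediction for designed candidate compounds, and
    Lipinski/Veber/Egan/Muegge drug-likeness screening. A synthetic-data
    generator with known ground truth supports parameter-recovery and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
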