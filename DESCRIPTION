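Package: emligfit
Title: Density-Guided Fitting of Protein-Ligand Complexes into Cryo-EM Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and refining protein-ligand complex models in
    cryo-EM density maps. Simulates density from atomic models, scores and
    ranks candidate poses by masked model-to-map cross-correlation,
    rigid-body aligns models into maps by cross-correlation ascent, refines
    them with Langevin dynamics driven by the gradient of map similarity
    under a lightweight structure-native restraint field with adaptive force
    scaling, and evaluates results with per-entity cross-correlation
    accuracies and a protein-ligand interaction-energy monitor. Includes a
    fully synthetic, seeded fixture generator so the whole pipeline can be
    exercised without any experimental downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
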