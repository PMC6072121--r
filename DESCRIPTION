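Package: angiosprout
Title: Hybrid Cellular Potts / Reaction-Diffusion Model of Endothelial
    Sprouting in Fibrin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates angiogenic sprouting of an endothelial monolayer
    into a fibrin matrix with a hybrid cell-based/continuum model: a
    cellular Potts model for cell shape and motility, a ten-species
    plasminogen-plasmin-TGFbeta1 reaction-diffusion system for
    fibrinolysis, and a per-cell ordinary differential equation for
    membrane-bound uPAR.  A uPAR-plasmin-TGFbeta1 positive feedback loop
    selects tip cells in the monolayer and consolidates sprout invasion.
    Includes morphometric quantifiers (angiogenesis level, sprouting and
    fibrinolysis percentages, cell-cycle statistics), lattice fixture
    generators, and scripted parameter-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
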