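Package: bramax
Title: Biomechanical Planning and Evaluation of Bimaxillary Rotation Advancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for surgical planning of
    bimaxillary rotation advancement (BRA) in obstructive sleep apnea.
    Provides tetrahedral/triangulated mesh containers with STL, PLY, OFF,
    VTK-legacy and Gmsh I/O, a deterministic head/airway phantom generator,
    landmark-based rigid registration, translation of jaw-displacement plans
    into Dirichlet boundary conditions, a geometrically nonlinear
    St. Venant-Kirchhoff finite-element solver for soft-tissue deformation,
    a bijective surface-distance metric with relevant-region masking,
    palatal-plane airway cross-section morphometry, and cohort-level
    statistics (Sher criterion, paired t-tests, summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
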