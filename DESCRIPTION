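Package: wishplan
Title: Wishlist-Driven Prioritized Multi-Criteria Optimization for
    Automated Radiotherapy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated fluence-map optimization for two-phase whole-pelvis
    prostate radiotherapy driven by a prioritized planning protocol
    ("wishlist") of hard constraints and goal-directed objectives, solved
    by a lexicographic epsilon-constraint method over a linear
    dose-influence matrix.  Includes a seeded synthetic pelvis phantom with
    the full structure-geometry toolbox (margin expansion, shells, rings,
    boolean operations), a water-equivalent pencil-beam dose surrogate for
    equi-angular coplanar beams, LTCP/EUD/max/mean cost functions, DVH and
    plan-quality metrics (homogeneity and conformity indices, EQD2,
    clinical organ-at-risk protocol checking), and 3D gamma-index dose
    comparison for plan QA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
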