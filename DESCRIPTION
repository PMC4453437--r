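Package: gridcell3d
Title: Self-Organization of Three-Dimensional Grid Cells by Firing-Rate
    Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the self-organization of grid-cell firing maps in a
    three-dimensional environment, as in a bat exploring a cubic volume. A
    feed-forward network of threshold-nonlinear units with firing-rate
    adaptation, head-direction gating and recurrent collateral input learns
    from place-cell-like spatial inputs through Hebbian plasticity, producing
    multi-peaked periodic firing maps. The package also implements the
    companion variational model: plane-wave constructions of face-centered
    cubic (FCC) and hexagonal close packed (HCP) field arrangements, an
    adaptation kernel with closed-form Fourier transform, cost-function
    evaluation and minimization over grid spacing and layer-stacking
    anisotropy, and relaxation-curve fitting. Analysis tools include masked
    3D autocorrelograms, grid-spacing extraction, best-plane hexagonality
    scores, FCC/HCP long-range order scores, spike-triplet local gridness and
    population alignment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
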