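Package: osteoscaffold
Title: Lattice Scaffold Design, Synthetic Micro-CT Cohorts and Bone
    Ingrowth Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying scaffold-guided bone regeneration in a
    large-animal metaphyseal defect model. Generates parametric
    truss-lattice scaffolds (octet, orthogonal cubic, Poisson-disk
    stochastic), computes their apparent elastic modulus in arbitrary
    loading directions with a 3D Euler-Bernoulli frame solver and reports
    direction-sweep anisotropy, synthesizes a paired ovine cohort of
    micro-CT phantoms encoding injury-driven peripheral and strain-driven
    central osteogenesis (with beam-hardening halo artifacts), quantifies
    bone ingrowth as a fraction of scaffold pore volume by global and
    local-adaptive segmentation, scores peripheral and interior bone
    formation on virtual sections with a three-rater consensus rule, and
    provides exact paired Wilcoxon signed-rank tests, log-stiffness
    regression and responder classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
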