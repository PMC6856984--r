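Package: lvemu
Title: Statistical Emulation for Fast Parameter Inference in a Left-Ventricle
    Biomechanics Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process surrogate modelling for inverse parameter
    estimation in a Holzapfel-Ogden model of passive left-ventricle
    mechanics. Trains emulators on precomputed simulator runs over a Sobol
    space-filling design and estimates the four reduced constitutive
    parameters from a 25-dimensional observation (24 circumferential strains
    plus end-diastolic volume) by minimising a surrogate loss. Provides two
    emulation strategies (output emulation and loss emulation), two
    interpolators (local K-nearest-neighbour Gaussian processes and low-rank
    eigendecomposition Gaussian processes), Euclidean and Mahalanobis loss
    functions, Hessian-based uncertainty quantification with stretch-stress
    confidence bands, and a benchmark harness comparing the eight method
    combinations. A fast analytic stand-in simulator built on the same
    constitutive law supports desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
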