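Package: meshlift
Title: Fidelity Augmentation of Coarse-Mesh Drug-Transport Simulations by
    Gaussian-Process Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Solves a two-dimensional reaction-diffusion model of
    drug-coated-balloon delivery to the arterial wall on a hierarchy of
    nested, longest-edge-bisected triangular meshes, and trains a
    Gaussian-process (Kriging) surrogate on nearest-neighbour features of
    coarse-mesh solutions to predict refined-mesh solutions at a fraction
    of the cost of direct simulation. Includes the finite-element solver
    (P1 elements, sparse BDF time stepping), longest-edge mesh refinement
    with node nesting, neighbourhood feature construction under cityblock,
    Euclidean and Mahalanobis metrics, concentrated maximum-likelihood
    Gaussian-process fitting via the DIRECT global optimizer, and a
    cross-validated RMSE evaluation pipeline with reference errors between
    refinement levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
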