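Package: growdom
Title: Exact and Numerical Solutions of Coupled Linear Reaction-Diffusion
    Equations on a Uniformly Growing Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves systems of coupled multispecies linear reaction-diffusion
    equations on a uniformly growing one-dimensional domain 0 < x < L(t),
    modelling successive generations of diffusing, proliferating (or
    differentiating) cells. Provides exact truncated Fourier-series solutions
    built on a boundary-fixing (Lagrangian) coordinate transformation and the
    Sun-Clement uncoupling transformation, closed-form limits for repeated
    proliferation rates, an independent per-mode matrix-exponential solver
    valid for any rate pattern, and an implicit finite-difference reference
    solver. Includes a truncation-error study and a command-line interface
    driven by YAML configuration files.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
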