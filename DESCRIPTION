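Package: biofilmTW
Title: Travelling Waves in a Degenerate PDE-ODE Model of Cellulolytic Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the travelling-wave analysis of a coupled PDE-ODE model
    of cellulolytic biofilm growth with doubly degenerate nonlinear diffusion
    and Monod substrate kinetics. Provides closed-form model functionals and
    existence-condition checks (residual substrate level, nullcline landmarks,
    the integral criterion for wave existence), a phase-plane shooting solver
    that computes the wave profile and speed by adaptive Runge-Kutta
    integration and bisection on the speed, a conservative finite-volume
    simulator of the full system in one and two space dimensions with
    front-tracking wave-speed estimation, and a shooting/continuation solver
    for the heteroclinic boundary-value problem used to trace bifurcation
    curves of wave speed against consumption rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
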