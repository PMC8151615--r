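Package: oscnoise
Title: Stochastic Dynamics and Spectral Entropy of Coupled Oscillator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study how intrinsic noise affects small networks of
    mutually connected oscillating processes. Builds two model families (a
    two-variable nonlinear limit-cycle oscillator and a scalable linear system
    of coupled oscillators wired by a squared-index-distance matrix), analyses
    their linear stability (eigenvalue curves, Hopf bifurcation points located
    by bisection, one-parameter bifurcation diagrams), converts the
    deterministic rate terms into event channels for exact Gillespie
    stochastic simulation, and quantifies the resulting trajectories through
    one-sided power spectral densities and normalized spectral entropy.
    Includes orchestration for the entropy-versus-system-size experiment and a
    linear scaling fit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
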