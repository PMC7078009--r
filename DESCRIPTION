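Package: surfhop
Title: Surface-Hopping Dynamics and Ensemble Kinetics on Linear Vibronic
    Coupling Models with Spin-Orbit Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory surface hopping in the spin-mixed (fully diagonal)
    basis on analytic linear vibronic coupling (LVC) models of coupled
    singlet and triplet manifolds, in the style used to study ultrafast
    intersystem crossing of thionated heteroaromatics such as
    2-thiopyridone.  Provides Wigner sampling of harmonic ground-state
    initial conditions, velocity-Verlet nuclear propagation with
    local-diabatization (overlap) amplitude propagation, fewest-switches
    hopping with energy-based decoherence correction, ensemble population
    analysis with a nine-rate kinetic network fit and single-exponential
    manifold lifetime fits, hop-count bookkeeping, and normal-mode
    projection analysis of hop-inducing geometries, vibrational coherence
    and bond lengths.  Reads Molden-style frequency files and multi-frame
    XYZ trajectories; all analyses are reproducible from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
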