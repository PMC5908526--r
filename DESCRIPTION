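Package: spermfilm
Title: Flagellated-Swimmer Suspensions in Periodic Thin Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of suspensions of model sperm cells in
    quasi-two-dimensional liquid films. Each swimmer is an inextensible
    elastic flagellum, discretized as constrained segments and driven by a
    travelling preferred-curvature wave, attached to an oblate cell head.
    Hydrodynamics are resolved with the force-coupling method (FCM): forces
    and torques are spread onto a periodic grid with Gaussian envelopes, the
    Stokes equations are solved spectrally, and body velocities are obtained
    by envelope averaging. A resistive-force-theory backend with calibrated
    drag coefficients isolates the role of hydrodynamic interactions. The
    package includes the implicit BDF2/Broyden time integrator with midplane
    restriction, steric interactions, stochastic lognormal modulation of
    undulation frequencies, and analysis tools: force dipole/quadrupole
    moments, polar and nematic order parameters, fluid energy spectra and
    centre-of-mass velocity spectra with low-pass filtering, pair
    displacement maps, and cluster statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
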