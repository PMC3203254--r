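Package: rta
Title: Receptor-Toxin-Antibody Reaction-Diffusion Kinetics Around a Single Cell
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates competitive receptor-toxin-antibody (RTA) kinetics for a
    spherical cell immersed in a toxin-antibody solution. Solves the coupled
    reaction-diffusion equations for toxin, antibody and toxin-antibody complex
    on a spherical shell with an implicit finite-difference scheme, coupled to a
    surface receptor-occupancy equation with internalization; also provides the
    well-mixed-solution (WMS) reduction as a mass-action ODE system, the antibody
    protection factor psi(t), five saturation estimators for its long-time limit,
    and closed-form transport diagnostics (conductance, bioavailability number,
    effective diffusivity, asymptotic protection factor) for classifying
    diffusion-limited versus kinetically limited toxin uptake.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
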