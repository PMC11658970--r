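Package: searchcoil
Title: Search-Coil Detection Modeling for Superparamagnetic Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational model of magnetic-nanoparticle detection by a
    perivascular search coil. Implements Langevin and scalar Jiles-Atherton
    magnetization models with material presets for iron oxide and cobalt
    ferrite, the drive field of a mains-powered solenoid, closed-form and
    quadrature magnetic-dipole flux through a circular coil, Carreau
    non-Newtonian blood rheology with a steady pipe-flow solver, induced-EMF
    synthesis for single particles and seeded particle ensembles (arterial
    pulse trains and venous counter-flow noise), and detection-limit and
    dose-safety analysis across voltmeter sensitivities and particle sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
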