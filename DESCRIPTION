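Package: mdtsim
Title: Magnetic Drug Targeting Simulation in a Weibel Airway Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates magnetic drug targeting (MDT) of aerosolised magnetic
    drug particles in an idealised G0-G3 Weibel airway tree obstructed by an
    epithelial wall tumor, using a fully magnetized bulk superconducting
    magnet as the external field source. Provides Bean critical-state trapped
    field calibration, Biot-Savart field maps of azimuthal current cylinders
    via complete elliptic integrals, a semi-analytic laminar airflow surrogate
    built on a Hagen-Poiseuille resistance network, Lagrangian particle
    transport with Schiller-Naumann drag and magnetophoresis, and particle
    deposition efficiency (PDE) analysis across parameter sweeps (particle
    diameter and permeability, breathing rate, tumor size, location and angle,
    magnet dimensions, distance and operating temperature).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
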