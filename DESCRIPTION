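Package: trpgating
Title: Eight-State Allosteric Voltage and Temperature Gating of TRP Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium and kinetic analysis of thermo-TRP channel gating with
    an eight-state allosteric model in which a voltage sensor, a temperature
    sensor and the pore gate are coupled by allosteric factors. Provides the
    closed-form open probability and open-probability landscapes over voltage
    and temperature, master-equation simulation under arbitrary piecewise
    voltage/temperature stimulation protocols, Boltzmann conductance-voltage
    fits, mono/bi-exponential relaxation fits with weighted time constants,
    Arrhenius/Q10 analysis, a seeded population-based constrained global fit
    of the allosteric parameters, and a synthetic whole-cell recording
    generator for validating every estimation stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
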