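Package: memstress
Title: Lateral Stress Profiles of Lipid Bilayers from a Diffuse-Interface Model
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form lateral stress profiles s(z) of fluid lipid bilayer
    membranes in a diffuse-interface (phase-field) description, parameterized
    by the Canham-Helfrich elastic constants: tension, bending rigidity,
    bilayer spontaneous curvature and Gaussian modulus.  Provides the tanh
    kink profile and its identities, the five stress components and their
    moments (including the tension-dependent correction to the second
    moment), radial energy quadratures for large spherical vesicles with
    their sharp-interface limits, monolayer-bilayer consistency relations,
    extraction of elastic constants from tabulated stress profiles, profile
    file I/O with unit conversion, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
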