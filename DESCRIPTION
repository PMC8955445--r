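Package: formosim
Title: Ribose Synthesis in Carbonaceous Planetesimals by a Coupled
    Thermal and Thermochemical Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the aqueous formose synthesis of ribose inside the
    parent bodies of carbonaceous chondrites. Couples a one-dimensional
    thermal evolution model of porous rock-ice planetesimals heated by
    radionuclide decay with a Gibbs-energy equilibrium treatment of a
    simplified formose reaction (formaldehyde plus glycolaldehyde to
    pentose), applies laboratory-derived catalyst yield factors for the
    ribose fraction among pentoses, and converts molar abundances to
    bulk-mass parts-per-billion for comparison with concentrations
    measured in carbonaceous chondrites. Includes a synthetic-scenario
    generator for composition ranges and toy temperature histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
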