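Package: pulserad
Title: Pulse-Radiolysis Spectral Resolution and Radical Kinetics for
    Thioether Peptide Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the radiation chemistry of hydroxyl-radical attack on
    thioether-containing model peptides: radiation-chemical yields (Schuler
    scavenging formula, thiocyanate and Fricke dosimetry), multicomponent
    resolution of transient absorption spectra into per-species G-values by
    non-negative least squares against a reference-spectrum library,
    mass-action simulation of the sulfur radical-cation reaction networks,
    exact-mass and diastereoisomer accounting of radical-coupling products,
    and a synthetic-data generator that emulates N2O-saturated aqueous pulse
    radiolysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
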