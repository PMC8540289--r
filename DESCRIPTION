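Package: osmoflux
Title: Passive Water and Proton Transport Across Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of passive water and proton transport across lipid
    bilayer membranes. Implements a delayed-pore-opening model of osmotically
    driven vesicle shrinkage, parameterization of stopped-flow light-scattering
    kinetics (deflection time, stage-II slope, plateau intensities, osmotic
    water permeability), flicker-noise spectroscopy of giant unilamellar
    vesicle contours for membrane bending rigidity, windowed slope estimation
    of transmembrane proton flux from fluorescence kinetics, and the
    correlations linking pore-opening delay to osmotic pressure difference and
    membrane mechanics. A synthetic-data layer emulates the stopped-flow
    instrument and the fluorescence microscope so the full pipeline runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    pracma,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
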