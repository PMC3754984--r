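Package: sprcell
Title: Optical Modeling and Multi-Parameter Signal Analysis for Surface
    Plasmon Resonance Living-Cell Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation of full surface plasmon resonance (SPR)
    angular reflectance spectra for layered cell-monolayer stacks in the
    Kretschmann configuration, using the 2x2 characteristic (transfer)
    matrix method with complex refractive indices.  Extracts the
    multi-parameter SPR signal set (main SPR peak angular position and
    minimum intensity, total-internal-reflection angle and intensity,
    waveguide nodes) from angular spectra, turns time series of spectra
    into sensograms, and classifies drug-cell response patterns into
    mechanistic scenarios (paracellular-like, transcellular-like,
    accumulation-only, spreading).  Includes a seeded synthetic-sensogram
    generator emulating injection/rinse drug-stimulation protocols, file
    readers and writers for instrument-style angular-scan exports, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
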