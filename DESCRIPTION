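Package: aodprint
Title: Planning and Simulation of Aspiration-on-Demand Multimaterial
    Hydrogel Printing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for planning and verifying multimaterial extrusion
    printing of hydrogels by sequential aspiration of inks into a single
    glass capillary. From a labeled layer pattern it decomposes each layer
    into parallel filaments, extracts ordered single-ink segments per
    filament, converts segment lists into aspiration/deposition step
    sequences with plunger displacements and transition-zone waste steps,
    emits G-code, and verifies plans with a virtual printer that
    reconstructs the deposited label map under last-in-first-out capillary
    semantics. Also implements the associated ink physics: Ostwald
    power-law viscosity fits, storage/loss-modulus crossover (gel point)
    detection, small-strain Hookean modulus fits, series-circuit effective
    conductivity of segmented filaments, a reservoir-temperature
    printability window, and a lumped Newtonian-cooling check for ink
    switching. Synthetic fixture generators reproduce the canonical test
    patterns (nested squares, conductivity gradient, two-layer "T",
    striped cell pattern) and measurement curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
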