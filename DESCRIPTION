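Package: grassim
Title: Grassland Management, Carrying Capacity and Productivity Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Process-oriented simulation of managed grasslands at daily time
    step on a synthetic grid: a minimal grass growth substrate with a
    saturating nitrogen-addition response of photosynthetic capacity, mowing
    and grazing rules with biomass thresholds and recovery logic, iterative
    optimization of stocking rate and grazed fraction (livestock carrying
    capacity), year-end adaptive adjustment of livestock density to forage
    surplus or deficit, a factorial experiment protocol attributing
    productivity trends to CO2, climate and nitrogen drivers, a 2^4
    parameter-uncertainty ensemble, and regional aggregation with model-data
    agreement statistics for grass-fed livestock numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
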