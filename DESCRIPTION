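Package: cowgas
Title: Headspace Gas Balance Analysis and Simulation of CO-Driven
    Hydrogenogenesis in Closed Serum Bottles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying biological water-gas-shift activity
    (CO + H2O -> CO2 + H2) from closed serum-bottle cultivations. Converts
    time series of headspace pressure, gas-chromatography mole fractions and
    optical density into per-species molar amounts via the ideal gas law,
    corrects cumulative consumption/production for the gas and liquid removed
    at each sampling event, and derives summary statistics (H2/CO yield, H2
    onset time, O2 depletion time, growth maxima). Includes a mechanistic
    kinetic simulator of a facultatively anaerobic carboxydotroph (aerobic
    growth and respiration, O2-inhibited water-gas shift, aerobic CO
    oxidation, formate-hydrogenlyase H2) that emits synthetic measurement
    series with realistic sampling withdrawals and noise, plus comparative
    locus genomics arithmetic: pairwise local protein alignment, a percent
    identity/coverage orthology rule, average amino acid identity, and locus
    G+C deviation screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
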