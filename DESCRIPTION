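Package: procleave
Title: Mass-Balance Analysis and Simulation of Processive Proteolysis by
    Gamma-Secretase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the branched, processive proteolysis of
    the amyloid precursor protein fragment C99 by wild-type and familial
    Alzheimer's disease (FAD)-mutant gamma-secretase. Converts mass-spectrometric
    coproduct measurements (AICDs and tri-/tetrapeptides) into concentrations via
    internal-standard calibration curves with limit-of-detection censoring,
    reconstructs all amyloid-beta intermediate pools by mass balance, computes
    per-step cleavage efficiencies with quality-control flagging, and simulates
    the two-branch trimming pathway (including stalled enzyme-intermediate
    occupancy) to generate synthetic replicate data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
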