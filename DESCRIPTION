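Package: p300iota
Title: Quantitative P300 EEG Source Analysis and Regional Charge Observables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for quantitative analysis of P300
    event-related potentials: spherical-head forward modelling, synthetic
    oddball-experiment simulation, epoching and artifact rejection, the
    sLORETA standardized minimum-norm inverse solution, aggregation of
    cortical current estimates to Brodmann-area time courses on a 5 ms
    grid, and computation of iota, the electric charge that flowed through
    each area in the 280-600 ms post-stimulus window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
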