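Package: fpvstag
Title: Frequency-Tagged Oddball Analysis for Fast Periodic Visual Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fast-periodic-visual-stimulation (FPVS)
    oddball experiments on multi-sensor magnetoencephalography-style recordings.
    Generates stimulus sequences and synthetic frequency-tagged epochs (steady-state
    response at a base rate, category-oddball response at a subharmonic, spatially
    smooth topographies, 1/f background noise), quantifies discrimination responses
    as baseline-corrected spectral amplitude at the oddball frequency, and assesses
    them with paired cluster-based permutation tests on sensor adjacency graphs,
    Hedges g effect sizes, and JZS Bayes factors with evidence tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
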