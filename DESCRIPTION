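Package: socialnull
Title: Permutation Null Models for Animal Social Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of animal social networks from group-by-individual,
    focal-sample and trajectory data, together with the permutation null models
    used to test hypotheses on them: node and restricted node permutations, edge
    permutations, pre-network data-stream (checkerboard) swaps with time,
    location and phenotype restrictions, focal-sample swaps, and day-shuffle
    nulls for autocorrelated movement data. Provides permutation significance
    testing with two-tailed p-values, (MR)QAP dyadic regression with pluggable
    null models, simultaneous two-network comparison, and synthetic-data
    generators that emulate gambit-of-the-group, focal-follow and GPS sampling
    with a controllable sex effect on sociality and a controllable observation
    bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
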