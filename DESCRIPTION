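Package: ribolandscape
Title: Population Genetics and Kinetics Toolkit for Directed Ribozyme Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro evolution experiments on ligase
    ribozymes: closed-form statistics of partially randomized (doped) RNA
    libraries, round-by-round high-throughput sequencing population analysis
    (abundance accounting, greedy Hamming clustering, distance-from-parent
    spectra, abundance trajectories), quasi-neutral mutational path finding on
    Hamming graphs of observed sequences, ligation kinetics fitting (first-order
    k_obs, Mg2+ Hill binding, pH-rate slopes), grouping of RNA secondary
    structures into folds along a mutational path, and a seeded synthetic-data
    generator that emulates activity-dependent selection rounds and noisy
    kinetic measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    Biostrings
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
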