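Package: spikewm
Title: Spike-Train Burstiness Analysis for Trial-Structured Working-Memory Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spiking irregularity ("burstiness") in
    trial-structured multi-unit recordings from a Sternberg working-memory
    task: the refractoriness-corrected local variation statistic (LvR) on
    single and combined spike trains, adaptive change-point detection,
    population-burst detection with sparsity and composition descriptors,
    mean-matched Fano factors, and burstiness-stratified pseudo-population
    decoding with linear support vector machines.  A gamma-renewal
    synthetic-session generator with injectable workload, burst and
    response-time effects supports calibration and power analysis without
    access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
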