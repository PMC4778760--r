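Package: sweepfdr
Title: Demography-Aware Genome Scans for Selective Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based genome scans for recent positive selection in a
    two-population design (a domesticated or bottlenecked focal population
    contrasted against its wild relative), calibrated against coalescent
    simulations of an explicit demographic model. Computes nucleotide
    diversity, between-population diversity, Hudson-style FST, and Tajima's D
    in overlapping sliding windows; converts the three sweep contrasts
    (log diversity ratio, FST, Tajima's D difference) into empirical p-values
    against a simulated neutral null, Benjamini-Hochberg q-values, and a
    composite-of-multiple-signals score; merges significant windows into
    ranked candidate regions; and contrasts the model-based scan with a
    demography-free empirical-percentile outlier scan. Also includes
    lineage-specific fixed-site analysis, gene-set fold-enrichment tests, and
    a self-contained synthetic-data generator (coalescent genomes with
    injected sweep loci) used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with msprime, numpy and pandas, available
    as 'python' on the PATH (override with option 'sweepfdr.python' or
    environment variable SWEEPFDR_PYTHON).
Config/testthat/edition: 3
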