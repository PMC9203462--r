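Package: abbskit
Title: Simulation and Quantification Toolkit for Anchor-Based Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and analysis toolkit for Anchor-Based
    Bisulfite Sequencing (ABBS) and Whole Genome Bisulfite Sequencing (WGBS).
    Generates synthetic bacterial (Dcm CCWGG) and mammalian-like (CpG-island,
    bimodal) methylomes, simulates the bisulfite-conversion / anchored-priming
    wet-lab chain down to paired-end FASTQ with a truth sidecar, performs
    truth-based per-cytosine methylation calling with Bismark-style trimming,
    and implements the downstream quantification procedures: conversion QC on
    an unmethylated spike-in, strict-threshold methylated-site calling, bin
    coverage and classification, motif meta-profiles, read-position statistics,
    subsampling sensitivity curves, correlation procedures, and region overlap
    fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
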