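Package: argoslice
Title: Simulation and Analysis of AGO4 siRNA Loading, Slicing and
    RNA-Directed DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying Argonaute 4 (AGO4) small interfering RNA
    (siRNA) biology in the plant RNA-directed DNA methylation (RdDM)
    pathway. Provides a deterministic kernel for siRNA duplex geometry and
    Argonaute slicing (cleavage of the substrate bond opposite guide
    positions 10 and 11), a seeded generator of synthetic genomes,
    Pol IV/RDR2/DCL3-style small RNA libraries and bisulfite methylomes,
    population-level small RNA profiling (size distributions, positional
    nucleotide matrices, signature classification, per-locus abundance),
    duplex pairing-registry spectra with a randomized-start null library,
    slicing-fingerprint detectors (shared 5' ends of 12- and 23-nt RNAs,
    the position-10 uridine signature of sliced target fragments), and a
    windowed bisulfite differential-methylation caller with single-linkage
    merging and siRNA association. All analyses run on synthetic data with
    no downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
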