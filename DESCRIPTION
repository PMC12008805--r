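Package: bitrexkit
Title: Simulation and Long-Read Genotyping of Tandem Gene Array Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying break-induced-replication-driven expansion and
    recombination-driven contraction of tandem gene arrays. Provides a stochastic
    per-lineage population simulator of array copy-number dynamics, the
    second-order contraction kinetics model (closed form, copy-number alteration
    per generation, rate-constant fitting with bootstrap uncertainty), spanning
    long-read selection and automated dot-plot repeat-unit counting with
    ascertainment-bias correction, masked-depth copy-number estimation with
    background normalization, a split-read rearrangement screen, and a synthetic
    data generator (genomes, long reads, qPCR-like copy-number series, engineered
    rearrangements) with truth tables for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
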