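Package: chipdep
Title: Classification of ChIP-Seq Binding Sites by Cofactor-Dependent
    Signal Depletion
Version: 0.1.0
Authors@R:
    person("chipdep", "maintainers", email = "chipdep@example.org",
           role = c("aut", "cre"))
Description: A desk-scale ChIP-seq differential-binding pipeline for
    two-genotype insulator-protein experiments. Calls enriched peaks
    against a preimmune control with a local-lambda Poisson model,
    filters blacklisted regions, assesses replicate reproducibility with
    ENCODE-style rescue and self-consistency ratios, scans peak windows
    with a position weight matrix at an exact tail-probability score
    threshold, computes per-peak RPKM signal tables and log2 fold
    changes between genotypes, detects depleted sites with an iterative
    one-sided Grubbs outlier procedure, and partitions sites into
    motif/depleted groups with profile, ranked-signal and
    co-localization summaries. Includes a seeded synthetic ChIP-seq
    generator with ground-truth annotations so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    methods,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
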