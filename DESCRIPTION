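Package: evopool
Title: Simulation and Analysis of Pooled-Isolate Resequencing for In Situ
    Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking mutations in evolving bacterial populations
    sampled as pooled isolates from sealed soil chambers buried in field
    sites. Provides a seeded synthetic-experiment generator (ancestral
    genome with paralogous gene copies, two-phase Wright-Fisher dynamics
    with dormancy, 100-isolate pool sampling, error-bearing aligned reads,
    and a drifting contaminant community), a pool-aware pileup variant
    caller with coding-effect annotation, cross-sample mutation census
    utilities (k-of-n shared-mutation classification, Venn partitions,
    site-unique gene parallelism, N:S ratios), read-backed linkage and
    paralog best-match checks, baseline-relative frequency-shift statistics
    (ANOVA, Tukey HSD, abiotic correlations), and non-focal community
    analytics (Shannon diversity, Bray-Curtis PCoA, source attribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    vcfR,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
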