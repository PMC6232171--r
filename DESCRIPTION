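Package: chromocata
Title: Scoring, Simulation and Cohort Analysis of Catastrophic Genomic
    Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes complex genome rearrangements
    (chromothripsis and chromoanasynthesis) from copy-number segments and
    structural-variant junctions. Implements per-chromosome scoring based on
    copy-number switch counts within a sliding window, oscillation
    statistics and a breakpoint-clustering test; junction-microhomology
    extraction, binning and beta-regression group comparison to infer the
    end-joining pathway active at the breakpoints; supervised mutational
    signature decomposition of 96-channel catalogs by non-negative least
    squares with cross-genome trinucleotide renormalization and a
    cosine-similarity fit criterion; and cohort-level exact association
    tests with false-discovery-rate control. A seeded simulator generates
    shattered-and-religated derivative chromosomes, gain-dominated
    template-switching events, pathway-conditioned junction homology,
    signature-mixture catalogs and binned read counts with purity and
    subclonal fraction, providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
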