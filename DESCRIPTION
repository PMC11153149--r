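Package: vdjscan
Title: Junction Analysis for HTGTS-V(D)J-Seq and 3C-HTGTS Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bait-anchored junction sequencing libraries from
    antigen-receptor loci. Implements cryptic recombination signal sequence
    (RSS) detection by heptamer/nonamer mismatch scoring, filtering of
    unannotated bona fide RSSs, 15-bp collapsing of coding-end junctions onto
    CAC cleavage sites, deletional/inversional orientation classification,
    library down-sampling and per-segment usage quantification with the
    associated comparison statistics, a restriction-site-anchored Poisson
    peak caller for 3C-HTGTS interaction profiles (moving-median background,
    Bonferroni summits, raw-P extension, multi-repeat robustness), and ±1 kb
    annotation of interaction peaks with CTCF-binding elements, E2A binding
    and transcription. A seeded synthetic-data generator emulates the
    statistical structure of both library types so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
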