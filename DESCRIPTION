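Package: srnatlas
Title: Small RNA Expression Atlas: miRNA Profiles, Editing, Strain
    Effects and piRNA Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-tissue, multi-strain small
    RNA-seq digital gene expression profiling. Quantifies miRNA hairpin
    arms (sense and antisense) from mapped reads, normalizes counts by
    an outlier-corrected mean, calls tissue-specific and tissue-avoidant
    miRNAs by a per-strain fold rule, detects candidate A-to-I editing
    as A-to-G substitutions in otherwise perfect reads, tests
    strain-differential expression with an abundance-ordered
    sliding-window Z statistic, characterizes the piRNA ping-pong
    signature (5'-5' overlap histogram and positional nucleotide
    content), and detects strand-specific piRNA clusters with
    core/extension/merge rules. Ships seeded synthetic-data generators
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
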