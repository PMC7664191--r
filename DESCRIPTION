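Package: enhancerMotifs
Title: Differential Transcription Factor Motif Enrichment in Condition-Specific Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies upregulated transcription factors whose binding motifs are
    differentially enriched between two condition-specific enhancer sets. Provides
    position weight matrix (PWM) site prediction with exact dynamic-programming
    score p-values, phylogenetic-footprint conservation filtering against an
    ortholog sequence map, motif redundancy collapsing, a proportion-ratio
    enrichment statistic with hypergeometric testing and Bonferroni correction,
    GREAT-style single-nearest-gene region association with binomial and
    hypergeometric term enrichment, predicted-target versus differential-expression
    overlap tests, and a seeded synthetic-data generator with planted ground truth
    for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
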