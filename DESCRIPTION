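Package: aneuarm
Title: Chromosome Arm Aneuploidy Scores and Tissue-of-Origin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes chromosome arm-level aneuploidy (imbalance) scores from
    discrete per-sample gain/loss calls and relates them to arm-wide mean gene
    expression, arm-wide DNA methylation, and the chromosomal distribution of
    tissue-specific cancer driver genes. Provides positive-correlation-count
    permutation tests based on pairing shuffles, K-nearest-neighbour
    tissue-of-origin classification from 39 arm-level features with a
    gene-aggregation permutation null, hierarchical clustering of tissues under
    alternative arm-level feature sets with cophenetic-distance comparison,
    Illumina 450K style arm-level methylation aggregation, and a synthetic
    cohort generator with a planted dosage effect for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
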