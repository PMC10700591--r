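Package: sgemap
Title: Analysis of Saturation Genome Editing Variant Effect Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for multiplexed assays of variant effect based on
    saturation genome editing (SGE) time-course screens. Per-variant read
    counts over replicated cell-culture timepoints are converted to log2
    fold-changes and depletion-rate trends with a per-variant negative
    binomial model, centred on synonymous and intronic controls, combined
    across the two guide libraries per exon (with PAM-codon replacement),
    and classified into functional classes (unchanged, enriched,
    fast-depleting, slow-depleting) using a two-dimensional Gaussian
    mixture. A supervised random-forest classifier scores variants for
    disease relevance with clinical confidence tiers, a quantitative
    ACMG/ClinGen rules engine with Tavtigian point combination models the
    impact on clinical variant interpretation, and companion modules cover
    trinucleotide mutational-model burden analyses, cancer driver-gene
    stratification and protein-structure summaries. A synthetic-data
    generator emulates the screen design so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    jsonlite,
    Biostrings,
    vcfR,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
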