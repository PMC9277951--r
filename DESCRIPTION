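Package: heterosisK
Title: Mid-Parent Heterosis and Expression-Pattern Analysis of Parent-Hybrid Trios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for heterosis of potassium content in hybrid
    crops and its transcriptomic basis. Computes K+ content from
    flame-photometer readings, mid-parent heterosis (MPH) per hybrid and
    timepoint, and screens strong and weak heterosis hybrids. Performs
    self-contained negative-binomial differential expression for
    parent-parent-F1 trios (median-of-ratios normalization, virtual
    mid-parent samples, per-gene Wald tests), classifies differentially
    expressed genes into twelve additive, dominant and overdominant
    expression patterns with grouped proportions, runs hypergeometric GO
    over-representation with Bonferroni control, filters homology-search
    hits into candidate potassium channel and transporter families, and
    validates fold changes with 2^-ddCt relative quantification. A seeded
    synthetic-data module with planted ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
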