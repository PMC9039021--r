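Package: raredrop
Title: Digital PCR Analysis of Rare Somatic Variants in Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Droplet-level analysis of two-channel digital PCR (dPCR)
    experiments for rare somatic variant detection in cell-free DNA, as
    used for histone H3 K27M testing in cerebrospinal fluid. Provides
    partition classification against fluorescence thresholds,
    duplicate-based positive/negative/ambiguous sample calling, Poisson
    concentration estimation with exact binomial confidence intervals,
    variant allele frequency estimation, a threshold-gated exponential
    preamplification model, a binomial low-template sampling model,
    dilution-series limit-of-detection analysis, Bland-Altman
    cross-platform agreement, cohort cfDNA summaries, and a synthetic
    droplet-level experiment simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
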