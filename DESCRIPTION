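Package: probindex
Title: Composite Inflammatory Index and Microbiome Analysis for a Paired Probiotic Pilot Trial
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a single-arm paired (pre/post supplement)
    probiotic pilot trial in siblings of type 1 diabetes patients. Computes a
    gene-set composite inflammatory index (I.I.com) from plasma-induced
    transcription arrays, classifies responders, performs paired per-transcript
    differential-induction testing with Benjamini-Hochberg false-discovery
    control and a signed-network upstream-regulator activation z-score, runs
    taxonomy-aware OTU-table analyses (rank collapsing, Shannon and richness
    alpha diversity, Bray-Curtis/PCoA beta diversity, LDA-effect-size
    differential abundance), applies paired rank statistics to cytokine and
    short-chain fatty-acid panels with the trial's change-table filter, and
    correlates dietary-fiber and CD4 T-cell covariates with index change. A
    seeded synthetic-cohort generator emulates every input so the full pipeline
    is testable without access to the trial's raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
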