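Package: barseqtox
Title: Bar-Seq Toxicogenomic Profiling, Enrichment and Competitive
    Growth Analysis for Pooled Deletion Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for genome-wide chemogenomic screens
    of pooled barcoded deletion libraries in fission yeast. Computes
    per-doubling growth-inhibition (GI) scores from barcode counts,
    standardizes them with robust Z-scores in normalized-IQR units,
    attaches tail-area false discovery rates and calls toxin-sensitive
    mutants under a two-screen concordance rule; performs hypergeometric
    term enrichment with Bonferroni correction; clusters mutant-by-toxin
    GI profiles with uncentered correlation and pairwise average linkage
    (Cluster 3.0 conventions, CDT/GTR/ATR and Newick export); and
    quantifies flow-cytometry competitive growth assays through a
    DAPI/scatter/doublet gating cascade with GFP-loss-corrected growth
    ratios. Includes synthetic-data generators for pooled exponential
    growth, multinomial barcode sequencing with substitution errors,
    annotation sets with planted enrichment, and mixture-model cytometry
    events, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
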