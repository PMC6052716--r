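Package: stickpop
Title: Population-Genomic Selection Tests for Marine Stickleback Standing Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying standing genetic variation and detecting
    selection across marine populations of threespine stickleback and similar
    systems. Implements per-locus and per-population diversity summaries and a
    RAD-seq style genotype filter cascade, the Weir-Cockerham theta estimator of
    F_ST (per locus, global and pairwise, with permutation significance),
    P_ST-F_ST and F_STQ-F_ST selection tests against a chi-square-scaled
    neutral null, Mantel isolation-by-distance tests over labelled distance
    matrices, and pseudo-observed-data (POD) calibrated F_ST outlier scans with
    marine-freshwater contrast comparison. A Balding-Nichols island-model
    simulator generates genotype and phenotype data with the statistical
    structure the analyses assume, so every stage can be exercised and
    calibrated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
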