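Package: dendroprov
Title: Tree-Ring Analysis of Forest Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dendrochronological analysis of common-garden provenance trials:
    Tucson/RWL ring-width input and output, cubic-smoothing detrending with a
    50 percent frequency cutoff, AR(1) prewhitening, biweight robust mean
    chronologies and their descriptive statistics (Gleichlaeufigkeit, mean
    sensitivity, inter-series correlation), Hargreaves potential
    evapotranspiration and climatic water balance, the standardized
    precipitation-evapotranspiration index (SPEI) via log-logistic
    probability-weighted moments, the 19 bioclimatic variables, pointer-year
    detection from Cropper values with Neuwirth intensity classes, pairwise
    principal component gradient analysis (PCGA) with Wilcoxon rank-sum
    testing of gradient ranks, hierarchical clustering of chronologies with
    the Mojena stopping rule, and ordination of bioclimatic profiles. A
    synthetic two-site trial generator with a tunable limiting-factor
    ("marginality") parameter makes the diminishing between-provenance
    differentiation under marginal climate reproducible without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
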