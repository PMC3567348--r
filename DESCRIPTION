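Package: fitscreen
Title: Chemical-Genetic Fitness Profiling of Pooled Yeast Deletion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for functional toxicogenomic screens in yeast:
    growth-curve area-under-curve (AUC) statistics and ICx estimation from
    plate-reader time series, differential strain sensitivity analysis (DSSA)
    of pooled deletion-strain barcode arrays (saturation adjustment, null-feature
    background correction, lowess pair normalization, robust alpha-outlier
    calling, exact binomial aggregation with FDR control, fitness scores),
    hypergeometric gene-set over-representation analysis against fixed or
    user-defined reference sets, and quantification of real-time GFP
    stress-reporter time courses via the Protein Expression Level Index (PELI).
    Seeded synthetic-data generators emulate pooled competitive growth with
    planted fitness effects, saturating hybridization, reporter plates, and
    Hill-type dose-response growth, giving every pipeline stage ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
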