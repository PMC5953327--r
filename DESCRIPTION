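Package: histphen
Title: Quality-Checked BLUEs from Historical Genebank Regeneration Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns highly non-orthogonal historical phenotype records
    collected during genebank seed regeneration into quality-checked best
    linear unbiased estimates (BLUEs) of accession performance. Provides a
    REML engine for linear mixed models with crossed/nested random factors
    and year-heterogeneous residual variances, a three-step quality control
    (plausibility rules, studentized-residual outlier detection with
    Bonferroni-Holm correction, and weather-parameter-index based exclusion
    of anomalous years), entry-mean heritability, a resampling study of
    MCAR/MAR missing-data patterns, and a synthetic-data generator that
    emulates the accession-by-year structure of historical collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    Matrix,
    stats,
    utils,
    ggplot2,
    generics,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
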