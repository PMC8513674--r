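Package: tntfinger
Title: Microbial Fingerprint Classification of Munition Contamination in
    Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the presence of the munition compound TNT
    (2,4,6-trinitrotoluene) in marine sediments from 16S rRNA
    gene-derived microbial community tables and geochemical covariates.
    Provides replicate averaging and guideline-based sample curation,
    compositional feature engineering (relative-abundance thresholding,
    taxonomic agglomeration, control-feature removal), repeated-split
    random-forest grid search scored by balanced accuracy, two variable
    importance schemes with p-values (corrected-impurity with a mirrored
    empirical null, and response-permutation importance), proximity-based
    ordination with environmental vector fitting, classification
    consistency and false-positive resilience analysis, a neural-network
    cross-algorithm validator, and a fully seeded synthetic data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    vegan,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
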