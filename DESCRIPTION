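Package: missprof
Title: Gene-Specific Functionality Profiling of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enumerates the complete single-nucleotide missense variant
    space of a coding sequence, derives functionality training labels from
    variant prevalence across independent cancer mutation databases (the
    cancer-shared-dataset rule), assembles functional-assay and
    computational score tables with median imputation, trains and tunes
    gradient-boosting and random-forest classifiers under a 60:20:20
    protocol with cross-validated random hyperparameter search, and
    validates predictions against ClinVar-style annotations,
    familial-cancer cohorts, population frequency tables and
    survival-stratified tumor cohorts. Includes seeded generators for
    every input so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    xgboost,
    ranger,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
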