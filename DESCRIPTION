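Package: toxsift
Title: Stepwise Curation of Aquatic Ecotoxicity Data with PNEC, ecoTTC and
    CTD Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable curation pipeline for heterogeneous aquatic
    ecotoxicity test records, built around a stepwise
    information-filtering (SIFT) workflow: relevance, validity and
    acceptability filters; chemical harmonization (unit conversion,
    SMILES desalting, salt exclusion, dummy-metal-ion grouping, category
    and solubility flags); taxonomic resolution and trophic-level
    assignment; rule-table-driven acute/chronic designation; exact
    duplicate removal and order-of-magnitude outlier detection against
    species and trophic-level geometric means. Downstream analysis tools
    derive predicted-no-effect concentrations (assessment-factor ladder
    or log-normal species sensitivity distribution), ecological
    thresholds of toxicological concern from PNEC distributions, and
    chemical toxicity distributions for a fixed receiver. A deterministic
    synthetic-data generator plants known duplicates, outliers, salts and
    rule violations with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
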