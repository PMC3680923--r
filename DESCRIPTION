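Package: clonalcn
Title: Clonality Testing for Paired Tumor Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether two tumors from the same patient are clonally
    related using genome-wide copy-number log-ratio profiles. Implements
    marker-level preprocessing (log-ratio computation against a normal-tissue
    reference, germline-CNV probe exclusion, block averaging), per-chromosome-arm
    single-change segmentation with gain/loss calling, a log-likelihood-ratio
    similarity statistic that weighs concordant changes by their cohort
    frequency and breakpoint overlap, and an empirical reference distribution
    built from cross-patient tumor pairs that yields p-values and a
    clonal / equivocal / independent classification. A synthetic-data
    generator produces paired and cohort profiles with known clonal structure
    for calibration and power assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
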