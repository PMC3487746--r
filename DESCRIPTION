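Package: pcrit
Title: Persistence-Criterion Analysis of Disease-Associated Variants Under
    Mutation-Selection Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether candidate susceptibility variants for a
    common, heritable disorder under strong negative selection can be
    sustained by mutation-selection balance. Computes the persistence
    threshold nu = (1 - s*p)*mu / ((1 - p)*s*p) from disease prevalence p,
    selection coefficient s and per-locus mutation rate mu; classifies
    case-control variant catalogs (risk-allele frequency difference
    d = mA - mU) into criterion-meeting, criterion-exceeding (protective) and
    non-positive classes with chromosome-arm aggregation; derives the
    case-control pair counts an association study needs to detect d of order
    nu; simulates the nuclear forward recurrence whose fixed point is nu and
    a maternal-lineage (mitochondrial) carrier model with
    heterozygote-advantage compensation; and generates synthetic catalogs and
    case-control allele counts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
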