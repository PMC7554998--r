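Package: polyfh
Title: Weighted LDL-Cholesterol SNP Scores and Polygenic Familial
    Hypercholesterolemia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying polygenic familial hypercholesterolemia (FH)
    in clinically diagnosed cohorts. Computes weighted LDL-cholesterol-raising
    SNP scores (11-, 8- and 6-SNP panels with APOE epsilon-genotype handling),
    refines SNP panels by case-control association (Hardy-Weinberg testing,
    allele-frequency tests, stepwise logistic regression), derives
    classification cutoffs from a control score distribution (percentiles and
    ROC/Youden), and estimates the fraction of FH patients with an
    identifiable monogenic or polygenic genetic cause. Includes a synthetic
    cohort generator (Hardy-Weinberg controls, frequency-shifted or
    liability-threshold-selected cases) so the full pipeline is testable
    without patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
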