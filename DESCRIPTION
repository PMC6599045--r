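Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics: reading and validating per-SNP association
    records, allele harmonization, per-instrument Wald ratio estimation,
    fixed-effects inverse-variance-weighted pooling with Cochran's Q and
    I-squared heterogeneity, leave-one-out and single-instrument
    sensitivity analyses, analytic power for binary outcomes,
    approximate-Bayes-factor colocalization, and a phenome-wide MR scan
    with Bonferroni family-wise error control. Includes a generator of
    synthetic two-sample summary statistics (and colocalization regions)
    with known ground truth, and a packaged worked example estimating the
    causal effect of circulating interleukin-18 on inflammatory bowel
    disease susceptibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
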