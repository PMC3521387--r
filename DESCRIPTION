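Package: epicontrast
Title: Prioritizing Epistatic SNP Pairs by Case/Control Correlation Contrast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive pairwise screening of genome-wide SNP genotype data for
    candidate epistatic interactions in case/control studies. For every SNP pair
    a genotype-dependence statistic rho is computed separately in cases and in
    controls from the 3x3 joint genotype table, and pairs are ranked by the
    contrast rho_diff = |rho_control - rho_case|, which cancels dependence shared
    by both groups (linkage disequilibrium, population structure) and retains
    disease-specific co-segregation. Top-ranked pairs receive Weibull-tail
    P-values and are summarized into hub-SNP reports. Includes a penetrance-model
    simulator (Hardy-Weinberg genotype sampling with rejection to fixed
    case/control quotas, single-table and interaction-network disease models) and
    an evaluation harness with scenario-specific accuracy rules and ROC curves.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
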