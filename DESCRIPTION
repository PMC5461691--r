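Package: nccdesign
Title: Design and Analysis of Matched Nested Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design and analysis of matched nested case-control
    (NCC) studies sampled from a prospective cohort. Implements greedy and
    optimal bipartite matching with exact factors, calipers on continuous
    factors and variable 1:k control ratios; caliper-sweep and covariate
    balance diagnostics; conditional logistic regression and the median
    paired difference with the Wilcoxon signed-rank test as rival analytic
    strategies; percentile-trimmed sensitivity refits; a with-replacement
    stratified resampling scheme that extends biomarker measurements to the
    full eligible cohort for an unconditional cohort analysis; and an
    overmatching diagnostic based on the sequential partial R-squared
    decomposition of a controls-only linear model of the biomarker on the
    match factors. A calibrated synthetic cohort generator emulating an
    older-adult surgical cohort with a single inflammatory biomarker (IL-6)
    makes every analysis reproducible without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
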