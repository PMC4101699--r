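Package: vista
Title: Divisive Shuffling for Patient Subtype Discovery from Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate patient subtypes by divisive stochastic
    shuffling: subjects are partitioned into two comparison groups plus a
    reservoir, and single-subject swaps are accepted whenever they increase
    the number of differentially expressed genes between the two groups.
    The objective is a two-class unpaired SAM (Significance Analysis of
    Microarrays) statistic with permutation-estimated false discovery rate,
    with a fast Welch-t/Benjamini-Hochberg alternative. Downstream tooling
    covers per-division clinical trait testing (Mann-Whitney U, Fisher's
    exact), co-occurrence analysis of significant traits under a binomial
    independence null with random-division baselines, single-trait binned
    differential expression, subtype construction with unique/common gene
    set decomposition, fold-change reporting, and gene-set
    over-representation analysis, plus a synthetic cohort generator with
    planted ground truth for end-to-end validation.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
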