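Package: mirvalve
Title: Integrated miRNA/mRNA Expression Analysis for Valve Disease Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrated microRNA/messenger-RNA
    expression analysis of case-control tissue studies, built around the design
    used for calcific aortic valve stenosis: per-feature Welch differential
    expression with Benjamini-Hochberg control, a thresholded Pearson
    co-expression network over differentially expressed miRNAs clustered by a
    from-scratch Markov Clustering (MCL) implementation, target-score-filtered
    miRNA-mRNA anti-correlation calling with a label-permutation null and exact
    Clopper-Pearson binomial confidence interval, gene-set over-representation
    via the two-sided hypergeometric test, degree/fold-change drug-target
    prioritization, and delta-Ct qPCR validation statistics including a
    NormFinder-style reference-gene stability decomposition. Includes a
    ground-truth synthetic-data generator so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    jsonlite,
    fgsea,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
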