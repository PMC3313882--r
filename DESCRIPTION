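Package: alloexpr
Title: Transgenerational Gene Expression Dynamics in Nascent Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of microarray gene expression in newly
    synthesized allopolyploids, their parents, and empirical mid-parent RNA
    mixtures. Provides a probe-level synthetic-data generator with planted
    expression patterns and hybridization-affinity artifacts, RMA-style
    normalization (normexp background correction, quantile normalization,
    median-polish summarization), MAS5-style present/absent detection calls,
    empirical-Bayes moderated pairwise contrasts among parents, mid-parent
    values and polyploids, classification of parental expression dominance
    (with mid-parent bias exclusion) and non-additive expression categories,
    transgenerational stochastic/heritable/persistent grouping with set-overlap
    summaries, and Fisher-exact term enrichment with FDR control.
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
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
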