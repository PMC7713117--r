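Package: erpcluster
Title: Spatiotemporal Cluster-Based Permutation Analysis of Event-Related
    Potentials with a Synthetic Longitudinal Study Generator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-arm longitudinal EEG studies with
    event-related potential (ERP) endpoints. Implements from scratch the
    max-statistic spatiotemporal cluster-based permutation test (independent,
    paired and repeated-measures F designs, with difference-of-differences
    interaction contrasts), cluster-masked Cohen's d effect sizes, trapezoidal
    cluster area-under-the-curve extraction and brain-behaviour Pearson
    correlation, plus the accompanying behavioural statistics (reaction-time
    coefficient of variation, split-plot mixed ANOVA, pooled-variance t tests
    with Hedges' g, Benjamini-Hochberg FDR, percentile outlier screening).
    A synthetic-data module generates sensor montages, AX-CPT task sequences,
    behavioural cohorts and multichannel EEG epochs with planted group-by-time
    effects and brain-behaviour couplings, so the whole pipeline is testable
    without any recorded EEG.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
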