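Package: amquant
Title: Quantification, Statistics and Display of Arbuscular Mycorrhiza Root Colonization
Version: 0.1.0
Authors@R:
    person("amquant", "developers", email = "amquant@example.org", role = c("aut", "cre"))
Description: Tools for quantitative root-colonization data from arbuscular
    mycorrhiza experiments. Reads and validates gridline-intersect percentage
    tables and Trouvelot score tables, computes the Trouvelot colonization
    indices (F, M, m, a, A) per biological replicate, collapses technical
    replicates, produces per-replicate and per-sample (mean and standard
    error) summary tables, performs per-variable Kruskal-Wallis tests with
    rank-based Fisher-LSD pairwise comparisons and multiple-testing
    correction, renders compact letter displays or asterisk annotations on
    faceted dotplots, barplots and boxplots, and exports tables and figures
    with fixed naming conventions. Includes seeded simulators for both
    scoring dialects and a command-line interface covering the full
    read-summarize-test-plot-save workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
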