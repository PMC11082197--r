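Package: InterDC
Title: Inter-Region Differential Correlation Network Analysis of Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds differential-correlation (DC) networks between pairs of
    tissue regions from paired bulk expression profiles of disease and control
    individuals. Cross-region gene pairs are screened for significant Spearman
    correlation in either group (Benjamini-Hochberg FDR plus an absolute
    correlation gate), tested for a change in correlation strength with the
    Fisher r-to-z difference test, and classified into gained-positive,
    gained-negative and lost-correlation edges. Includes reference-free
    cell-type correction via marker-gene surrogate proportion variables,
    Wilcoxon differential expression and DE-driven-edge accounting, hub and
    region-exclusivity summaries, bipartite Louvain module detection,
    hypergeometric over-representation analysis with a structure-preserving
    permutation null, and a synthetic-data generator with planted correlation
    rewiring and composition confounding for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
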