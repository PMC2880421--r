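Package: methcall
Title: Normal-Referenced Aberrant DNA Methylation Calling for Bisulfite
    Pyrosequencing Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of CpG methylation percentages from
    bisulfite pyrosequencing of candidate gene panels. Averages per-CpG
    methylation to gene-level values, calibrates a per-gene normal-tissue
    reference and scores tumour samples as hyper- or hypomethylated beyond
    mean +/- 2 SD, tabulates aberrant-methylation frequencies per diagnosis
    group, screens methylation levels against clinicopathological factors
    with permutation Mann-Whitney and Kruskal-Wallis tests under
    Benjamini-Hochberg false discovery rate control, quantifies
    co-methylation with permutation Spearman correlations, and computes
    qRT-PCR relative expression by the standard-curve method. A seeded
    synthetic-cohort generator with exported ground truth makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
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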