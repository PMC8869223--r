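Package: hepmeta
Title: Cross-Study Consensus Analysis of Offspring Liver Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Integrative re-analysis toolkit for multi-study transcriptomic
    comparisons of liver tissue from offspring of obese versus lean mothers.
    Implements per-comparison two-group differential expression with
    empirical-Bayes moderated t-statistics, cross-comparison consensus gene
    selection and ranking (effect-size and significance gates, Fisher p-value
    combination), top-250 up/down hypergeometric pathway enrichment with a
    cross-comparison consensus rule, histological quantification of steatosis
    (vacuole area fraction) and fibrosis (blue-stain area fraction), qPCR
    reference-gene normalization, oral glucose tolerance test areas under the
    curve, and Mann-Whitney group comparisons. A synthetic-data generator with
    planted ground truth (consensus genes, enriched pathways, vacuole and
    fibrosis fractions) makes every stage verifiable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
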