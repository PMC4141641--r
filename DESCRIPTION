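Package: apmskit
Title: Spectral-Count Interactome Filtering and Acute Expression-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of affinity purification
    mass spectrometry (AP-MS) experiments scored by spectral counting,
    together with the downstream assays that typically accompany them.
    Implements mock-background subtraction, abundance filtering,
    redundancy collapsing and molecular-weight normalized ranking of
    bait interactomes; detection-p-value filtering, quantile
    normalization, Welch t-testing and signed fold-change list assembly
    for two-condition expression microarrays; delta-delta-Ct relative
    quantification for qPCR; and hypergeometric/binomial overlap
    statistics for signed gene lists. A synthetic-data generator with
    planted ground truth makes every stage verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
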