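Package: mirconsensus
Title: Consensus miRNA-mRNA Regulatory Network Inference from Public
    Thyroid Cancer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds putative post-transcriptional miRNA:mRNA regulatory
    networks for papillary and anaplastic thyroid carcinoma by integrating
    literature vote-counting of miRNA deregulation, multi-algorithm target
    prediction consensus, cross-dataset differential-expression concordance
    and anti-correlation filtering. Downstream stages score the resulting
    target-gene lists with hypergeometric/EASE gene-set enrichment and
    associate target-gene alteration (Z-score classification) with clinical
    risk and overall survival (Kaplan-Meier, log-rank). A synthetic-data
    module plants recoverable signal in every input kind so the whole
    pipeline is testable without any database download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite,
    nortest,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
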