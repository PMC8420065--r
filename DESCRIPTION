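Package: emtrn
Title: Enhancer-Methylation-Mediated Target Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers target genes of differentially methylated enhancer
    regions (DMERs) from Illumina HM450K-style beta-value matrices and
    matched expression profiles, and assembles them into a competing
    endogenous RNA (ceRNA) regulatory network. The pipeline covers probe
    quality control and k-nearest-neighbour imputation, window-based
    enhancer region construction, empirical-Bayes moderated differential
    methylation testing, distance- and correlation-based enhancer-gene
    linking, a shared-miRNA hypergeometric screen, co-expression network
    assembly with hyper-/hypo-methylation subnetworks, maximal-biclique
    module mining, Cox risk-score survival screening with train/test
    log-rank validation, ROC biomarker evaluation, gene-set
    over-representation analysis, and drug-lncRNA target networks. A
    synthetic-study generator with planted, machine-readable ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    survival,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
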