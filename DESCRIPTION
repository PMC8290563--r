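Package: hmlnet
Title: Hepatic mRNA-lncRNA Proximity Network Screening and Expression
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens candidate cis-acting long non-coding RNAs for
    association with protein-coding genes by genomic proximity.
    Implements the full desk pipeline: differential-expression
    filtering, coding-potential screening of lncRNA candidates,
    hypergeometric gene-set over-representation with metabolic category
    tagging, window-based mRNA-lncRNA pairing on collapsed gene spans,
    construction of a combined protein-protein / pairing network with
    degree-centrality hub-pair shortlisting, and the downstream
    expression-validation statistics (delta-delta-Ct relative
    quantification, one-way ANOVA with pairwise post-hoc tests, Pearson
    correlation, bootstrap ROC/AUC, HOMA-IR, and tolerance-test area
    under the curve). A synthetic-data generator emulates every input
    with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
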