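Package: gsce
Title: Gene Set Correlation Enrichment Analysis for Two-Class Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether a list of differentially expressed genes (DEGs),
    and each individual DEG in it, is associated with named gene sets by
    measuring the enrichment of coexpressed gene pairs rather than bare
    membership overlap. From a two-class (control/case) expression matrix the
    package calls DEGs, builds a case-sample Pearson coexpression network at a
    user-chosen |r| threshold, and scores each (query, gene set) pair with an
    upper-tail hypergeometric test on coexpressed versus possible gene pairs,
    with Benjamini-Hochberg correction across gene sets. A Stouffer
    unweighted Z layer combines association significance across datasets or
    pathways, and a synthetic-data benchmark with planted DEGs and a planted
    coexpression module provides ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, NetworkEnrichment, DifferentialExpression,
    GraphAndNetwork, Pathways
RoxygenNote: 7.3.3
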