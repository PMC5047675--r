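Package: chromflow
Title: Integrative Analysis of ChIP-Seq Reproducibility, Enhancer Annotation,
    Expression and AP-MS Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrative regulatory
    genomics: replicate-consistency filtering of ChIP-seq peak calls with an
    irreproducible discovery rate (IDR) Gaussian-copula mixture model fitted
    by EM; five-class peak annotation (promoter, gene body, intergenic,
    poised and active enhancer) from histone-mark enrichment; signal profile
    matrices and occupancy correlation with hierarchical clustering;
    negative-binomial differential expression with size factors and BH
    correction, FPKM, PCA, and qPCR delta-Ct normalisation; AP-MS interactor
    calling (moderated statistic with permutation FDR) and anchor-relative
    stoichiometry with fraction-in-complex; and the cross-dataset overlap,
    dependency and direction-of-change analyses that tie them together.
    Ships a synthetic-data generator that plants ground truth for every
    stage so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
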