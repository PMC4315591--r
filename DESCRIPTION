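Package: woundarray
Title: Differential Expression, Set Logic and Positional Clustering for
    Wound-Healing Microarray Designs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for four-condition one-channel microarray
    experiments contrasting healing-engaged (JNK-signaling positive) cells
    against their non-engaged siblings in wounded and non-wounded Drosophila
    imaginal discs.  Provides non-specific intensity/IQR filtering, quantile
    normalization, median-polish probe-set summarization, empirical-Bayes
    moderated t-statistics with log-odds of differential expression,
    Benjamini-Hochberg FDR control, multi-contrast Venn set logic with
    sign-pattern subset classification, template-matching expression
    clustering on discretized profiles, chromosomal positional-cluster
    detection with permutation nulls, level-3 Gene Ontology hypergeometric
    enrichment, and a synthetic-data generator with planted truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
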