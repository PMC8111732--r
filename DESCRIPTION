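Package: theia
Title: Joint Discovery of miRNA-Gene Regulatory Comodules and Signed
    Interaction Weights
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements Theia, a joint optimizer that simultaneously learns
    miRNA/gene regulatory comodules by non-negative factorization of putative
    miRNA-gene interaction and protein-protein interaction matrices, and
    signed, strength-valued individual miRNA-gene regulation weights through a
    sigmoid-gated, variance-scaled regression.  All three sub-problems are
    minimized together by projected gradient descent.  The package also ships
    the synthetic benchmark generator the method is evaluated on (skew-normal
    module memberships, Gaussian expression with linear miRNA effects,
    controllable putative false-positive rate) and an evaluation suite:
    adjusted Rand index for comodule recovery, direction-aware
    precision/recall/F1 for interaction calls, precision-recall curves with
    AUPR, detection rate against validated interaction sets, and Fisher exact
    enrichment with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluate.R'
    'io.R'
    'nmf.R'
    'pipeline.R'
    'postprocess.R'
    'regulation.R'
    'simulate.R'
    'theia-package.R'
    'train.R'
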