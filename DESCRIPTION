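Package: ivccc
Title: Causal Cell-Cell Communication Inference from Paired Perturbation
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies treatment-induced cell-cell communication channels
    from paired pre/post-perturbation single-cell RNA-seq. Treatment is used
    as an instrumental variable to screen cross-cell-type differentially
    expressed gene pairs by two-stage least squares, Fisher-z conditional
    independence testing over ligand-receptor pairs nominates mediating
    channels, and results are assembled into gene expression modules and a
    communication network. Includes a synthetic tumor-microenvironment
    generator with planted channels, confounded decoy gene pairs and decoy
    ligand-receptor pairs for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
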