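Package: MRconcord
Title: Master Regulator Identification by Differential Connectivity
    Concordance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step statistical test for the existence and identity of a
    master regulator transcription factor from two-group (case/control)
    gene-expression data. Per-TF differential connectivity with the genes is
    combined with the pooled TF-TF correlation hierarchy through a Kendall
    concordance statistic; the maximum concordance over candidate TFs is
    assessed by a pooled-resampling bootstrap. Includes the hierarchical
    latent-factor simulator used for size and power calibration, Monte-Carlo
    drivers for empirical size, power curves and identification accuracy,
    delimited-text readers and writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, parallel, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: GeneExpression, Network, GraphAndNetwork, Transcription,
    StatisticalMethod
RoxygenNote: 7.3.3
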