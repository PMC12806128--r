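Package: DiffPert
Title: Conditional Diffusion Transformers for Chemical Perturbation
    Transcriptome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts post-perturbation bulk transcriptomes from a paired
    pre-perturbation (control) profile together with a text-encoded chemical
    perturbation and dose, using a multi-conditional denoising diffusion
    probabilistic model whose noise predictor is a transformer with
    cross-attention or adaptive layer-normalization condition fusion.
    Includes paired-control data structures built on SummarizedExperiment,
    log-normalization and differential-expression utilities, a deterministic
    text/fingerprint perturbation embedder, an R-squared and fold-change
    correlation evaluation suite at five grouping granularities,
    out-of-distribution drug/cell-line split benchmarks, and a synthetic
    perturbation data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineOB,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
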