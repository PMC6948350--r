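Package: longjrc
Title: Joint Longitudinal Regression and Classification with Structured
    Sparse Tensor Coefficients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a joint multivariate-regression and one-vs-all support
    vector machine model to longitudinal multimodal data (e.g. imaging
    measures, genotypes and cognitive scores observed at several visits).
    The coefficient tensor is regularized by an l2,1-norm (longitudinally
    consistent feature selection), a group l1-norm over modality blocks,
    and a trace norm on the unfolded coefficient matrix, and the composite
    objective is minimized by a multi-block alternating direction method of
    multipliers with closed-form proximal updates. Includes prediction,
    repeated cross-validation and hyperparameter-grid evaluation, biomarker
    ranking from coefficient magnitudes, and a synthetic-data generator
    with known ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
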