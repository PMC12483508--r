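Package: popcoding
Title: Population Coding Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for single-neuron and population-level analysis
    of two-photon calcium imaging recordings from visual cortex: neuropil
    correction, density-mode baseline (F0) estimation and dF/F, nonnegative
    deconvolution of calcium transients, trial alignment and response metrics
    (visual responsiveness, orientation tuning and OSI, maximum response,
    trial-to-trial reliability, pairwise/signal/noise correlations), lasso
    encoding models of stimulus, pupil and locomotion with partial-model
    variance partitioning, population-activity encoding models, balanced
    linear-SVM population decoding with multiclass AUROC and shuffle nulls,
    and linear mixed-effects group comparisons. Includes a synthetic-data
    generator that emulates control and knockout neural populations with
    known ground truth so every stage is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    e1071,
    pROC,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
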