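Package: claimformer
Title: Pre-Trained Transformer Models for Longitudinal Medical Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage pre-train/fine-tune framework for longitudinal
    administrative claims data. A transformer encoder over date-ordered
    medical visits is pre-trained on a large unlabelled claims corpus with
    two unsupervised objectives - next-visit code prediction and per-visit
    code-category prediction - and then adapted to small population-specific
    binary cohorts by full fine-tuning, frozen-encoder linear probes, or a
    from-scratch control. Includes a calibrated synthetic claims simulator
    (latent health-state Markov emission model), cohort selection with
    index-event truncation, AUC-based repeat-averaged evaluation, input and
    objective ablations, cross-corpus transfer experiments, and embedding
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    glmnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
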