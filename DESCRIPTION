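Package: trajrisk
Title: Multi-Horizon Cancer Risk Prediction from Longitudinal Disease-Code Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the risk of a low-incidence cancer from
    longitudinal hospital diagnosis-code trajectories. Ingests per-patient
    ICD-coded event histories, enumerates labelled partial trajectories with
    augmentation, exclusion windows and patient-level splits, and fits
    multi-horizon risk models (bag-of-codes, multilayer perceptron, gated
    recurrent unit and attention encoders over learned code embeddings with
    time-aware cosine positional weighting) using a masked multi-horizon
    cross-entropy loss. Includes the full evaluation machinery for rare-outcome
    risk models (AUROC/AUPRC with bootstrap confidence intervals, relative-risk
    curves over top-n operational points, F1 operational points,
    recall-by-time-to-event and surveillance-scenario arithmetic),
    integrated-gradients attribution of risk to individual diagnosis codes, and
    a seeded synthetic-cohort generator with planted hazard structure for
    end-to-end validation without access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
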