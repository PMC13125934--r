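Package: mmempathy
Title: Multimodal Empathy Analysis: Rating-Based Signal Detection, ERP
    Late Positive Potential, Heart Rate Variability, and Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis chain for multimodal empathy
    experiments combining behavioural ratings, event-related potentials
    (ERP) and electrocardiography (ECG). Implements rating-based
    signal-detection ROC curves and nonparametric AUC, EEG epoching and
    late-positive-potential (LPP) amplitude extraction, ensemble
    empirical mode decomposition (EEMD) denoising with extreme-point
    R-peak detection and time-, frequency- and nonlinear-domain heart
    rate variability (HRV) indices, and leave-one-out multimodal
    decoding of emotional state with ROC and Cohen's kappa. A synthetic
    cohort generator with known ground truth supports null calibration
    and parameter-recovery testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
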