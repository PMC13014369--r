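Package: sozpower
Title: Seizure-Onset-Zone Localization from Intracranial EEG Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Localizes the seizure onset zone (SOZ) from intracranial EEG
    recordings using multitaper band-power features computed over the early
    ictal period. Provides a preprocessing chain (artifact-channel removal,
    zero-phase notch filtering, common average reference, epoching), sliding
    window multitaper power spectral density aggregated into six canonical
    frequency bands, SOZ versus non-SOZ group statistics (power-over-time
    AUC contrasts with Bonferroni correction, decile tables and decile-ratio
    features), and two stacked random-forest ensembles with a penalized GLM
    meta-learner: one labelling electrodes as SOZ, one predicting
    post-operative seizure freedom. A synthetic iEEG cohort generator with
    known ground-truth SOZ channels and the eight canonical seizure-onset
    morphologies makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
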