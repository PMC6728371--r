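Package: icualarms
Title: Suppression of False Arrhythmia Alarms from ICU Bedside Monitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies life-threatening arrhythmia alarms (asystole, extreme
    bradycardia, extreme tachycardia, ventricular tachycardia, ventricular
    flutter/fibrillation) raised by ICU bedside monitors as true or false,
    using only the waveforms preceding the alarm. Implements waveform
    preprocessing (flat-line screening, polynomial baseline removal, arterial
    blood pressure abnormality criteria), wavelet-transform QRS detection,
    double slope-sum-function pulse-onset detection, amplitude-envelope based
    rejection of pacing spikes and T-wave over-sensing, signal quality indices
    and arrhythmia-specific features, cost-sensitive random-forest
    classification with out-of-bag permutation importance and forward feature
    selection, a rule-based bradycardia verifier, challenge-style scoring, and
    a deterministic synthetic vital-sign simulator with exact ground truth for
    end-to-end validation without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
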