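Package: nwreflex
Title: Laser-Evoked Nociceptive Withdrawal Reflex Analysis for Spinal Cord Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laser-evoked nociceptive withdrawal
    reflexes recorded by surface electromyography (EMG) in spinal cord
    injured (SCI) and non-disabled control (NDC) cohorts. Provides a
    seeded synthetic cohort generator (stimulus-locked two-channel EMG
    epochs, trial manifests, clinical tables), EMG conditioning
    (band-pass filtering, segmentation, rectification), threshold-based
    reflex burst detection with A-delta/C-fiber time-window
    classification, burst characterization (onset latency, area under
    the rectified curve, phase count), conduction-velocity estimation
    from inter-site latency shifts, and the nonparametric statistical
    battery relating reflex behavior to spasticity and neuropathic pain
    (Wilcoxon rank-sum with effect size r, Fisher's exact test with phi,
    eta coefficient, Kendall tau-b).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
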