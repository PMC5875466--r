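Package: dynaqa
Title: Log-File-Based Quality Assurance for Dynamic MLC Radiotherapy Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the actually delivered multileaf-collimator (MLC)
    sequence of a sliding-window IMRT field from per-bank delivery log files
    sampled every 55 ms, re-renders the delivered fluence and a forward dose
    distribution, and quantifies delivery errors. Provides readers and writers
    for control-point MLC sequence files and paired delivery logs, analytic
    MU-weighted fluence rendering, 2D gamma-index comparison with
    dose-difference and distance-to-agreement criteria, a deterministic
    parallel-beam dose engine with dose-volume histogram (DVH) metrics
    (D98%, D2%, Dmean) and chamber-volume dose, systematic MLC error
    injection (opening expansion, bank shifts, dropped segments), a seeded
    delivery simulator for validation studies, and QA statistics: per-leaf
    RMS position errors, dose-ratio correlation, the confidence limit
    |mean| + 1.96 SD, and action-level verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
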