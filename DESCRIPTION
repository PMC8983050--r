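Package: oddpred
Title: Oddball Stimulus Design and Predictive-Coding Index Analysis for
    Auditory Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing frozen oddball, cascade and many-standards
    tone sequences with optogenetic laser pairings, simulating Poisson
    spike-train recordings with known ground truth, extracting event-aligned
    firing rates and peristimulus time histograms, decomposing neuronal
    mismatch into prediction-error and repetition-suppression indices
    (iMM = iPE + iRS), classifying adapting and facilitating units,
    parsing recording sites into central and shell inferior-colliculus
    locations by tonotopy and tuning sparseness, and dispatching the
    accompanying statistical tests with effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
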