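Package: emgsynergy
Title: Muscle Synergy Extraction and Adaptation Analysis for Multi-Channel EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how motor modules reorganize during perturbation
    training. Conditions raw multi-channel surface EMG (high-pass, rectification,
    zero-phase low-pass), bins gait-cycle segments, and factorizes the resulting
    nonnegative muscle-by-time matrices with non-negative matrix factorization,
    selecting the synergy number by dual variance-accounted-for criteria. Synergies
    are pooled across subjects, grouped by hierarchical clustering under a
    subject-uniqueness rule, matched across adaptation stages with degrees-of-freedom
    based critical correlation thresholds, and screened for merging, fractionation,
    and weight modification via nonnegative least squares. Includes a synthetic EMG
    cohort generator with known ground-truth synergies, a subject-subsampling
    cross-validation of cluster robustness, and an end-to-end seeded pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
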