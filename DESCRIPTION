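Package: spindlesync
Title: Simulated MEG/EEG Sleep Spindles and Source-Space Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates simultaneous EEG (60 channels) and MEG (306 channels)
    recordings of stage-2 sleep spindles generated by two thalamocortical
    source systems on a folded-sphere cortical surrogate: a diffuse,
    cortex-wide synchronous ("matrix") system and multiple focal,
    asynchronous ("core") patch systems. Provides analytic spherical-head
    forward models (three-shell Legendre series for EEG, the Sarvas formula
    for MEG), noise-normalized minimum-norm (dSPM) inverse operators for
    EEG-only, MEG-only and combined data, and source-space synchrony
    statistics: mean pairwise correlation, between-modality correlation,
    Welch and MVDR (Capon) band coherence, and per-spindle maximum
    activation maps. A pipeline orchestrates the full multi-subject
    experiment and aggregates statistics spindles-within-subject, then
    across subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
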