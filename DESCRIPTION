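Package: mmnrvip
Title: Simulation and Analysis of Mismatch Negativity and Sustained
    Attention in a Drug Crossover Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing a dual-task
    psychopharmacology session in which auditory mismatch negativity (MMN)
    is recorded while participants perform the rapid visual information
    processing (RVIP) task. Generates non-overlapping digit and oddball
    tone schedules, simulates continuous multi-channel EEG with blink
    artifacts and condition-dependent deviance responses together with
    button-press behaviour, extracts MMN peak amplitude and latency via an
    epoch-average-subtract pipeline, scores sustained attention with
    signal-detection d-prime, and fits split-plot repeated-measures ANOVAs
    with Greenhouse-Geisser correction, Bonferroni pairwise follow-ups,
    change scores, and Pearson correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
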