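Package: cohortsim
Title: Process-Oriented Simulation of Spoken-Word Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates human auditory word recognition as a process unfolding
    in time. A waveform is converted to Mel-frequency cepstral feature
    trajectories, matched frame-by-frame against context-dependent
    three-state hidden Markov phone models arranged in a cohort prefix tree,
    and the resulting frame-normalized activations of words, cohorts and
    phonotactically licensed pseudo-words drive threshold-gap decision rules
    for word identification and lexical decision. Reaction times decompose
    into a decision component, an entropy-based (Hick-Hyman) choice component
    when no decision is reached by stimulus offset, and a constant execution
    latency. Includes a synthetic-speech world generator (phone inventories
    with known emission statistics, noise-excited stationary spectra,
    Zipf-distributed lexicons, segment-localized noise) so the full pipeline
    is testable end to end without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
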