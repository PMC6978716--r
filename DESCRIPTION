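Package: corticodyn
Title: Connectome-Constrained Neural Mass Dynamics with rsFC and EEG
    Microstate Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity by integrating
    Larter-Breakspear neural mass dynamics on a weighted structural
    connectome, forward-models the dynamics into BOLD signals
    (Balloon-Windkessel) and scalp EEG (lead-field projection), and scores
    parameter points (global coupling strength, excitatory/inhibitory
    threshold variance) against target resting-state functional
    connectivity matrices and EEG microstate maps. Includes a modified
    polarity-invariant k-means microstate algorithm with k-means++
    initialisation and segmentation smoothing, phase-locking value
    matrices, and synthetic generators for connectomes, lead fields and
    ground-truth microstate EEG so the full pipeline is testable without
    empirical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    pracma,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
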