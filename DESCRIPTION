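Package: scgaze
Title: Ensemble Coding of Eye-Head Gaze Shifts in the Superior Colliculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-unit activity recorded from the
    midbrain superior colliculus (SC) during rapid eye-head gaze shifts, and a
    forward simulator of the linear ensemble-coding model of the SC motor map.
    Includes the complex-logarithmic afferent/efferent mapping between
    gaze-shift vectors and SC map coordinates, static gain-field movement-field
    fitting by Nelder-Mead least squares, fixed and adaptive Gaussian-kernel
    spike-density estimation, dynamic phase-trajectory analysis of cumulative
    spike counts against straight-line gaze displacement, spike-density versus
    gaze-velocity correlations with session-wide shuffle nulls and
    beta-function fits, multiplicative (signal-dependent) spike-count noise
    characterisation, and a session-level analysis pipeline with plain-text
    session storage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
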