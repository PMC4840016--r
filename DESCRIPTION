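Package: ccepclean
Title: Model-Based Stimulation Artifact Correction for Cortico-Cortical
    Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes direct electrical stimulation artifacts from
    intracranial EEG recordings of cortico-cortical evoked potentials
    (CCEPs). The artifact is forward-modeled as the resistor voltage of an
    RC circuit representing the electrode-tissue interface driven by a
    square current pulse; a bank of down-sampled artifact templates over a
    grid of RC time constants and all sub-sample alignment shifts is fitted
    to each stimulation by linear regression and subtracted, preserving
    early (1-10 ms) response components that simple average-subtraction
    distorts. Includes a ground-truth synthetic CCEP simulator, the
    average-subtraction baseline method, and residual-power / latency-bias
    performance metrics with a benchmark driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
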