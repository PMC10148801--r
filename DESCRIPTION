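Package: mtladapt
Title: Single-Neuron and iEEG Analyses of Semantic Priming Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for distinguishing single-neuron mechanisms of
    neural adaptation (sharpening, fatiguing, facilitation) in a semantic
    priming task. Implements behavioral priming contrasts with reaction-time
    outlier exclusion, intracranial EEG preprocessing with median-ratio
    artifact rejection and event-related potential peak-latency contrasts,
    cluster-based permutation statistics for paired ERP comparisons,
    single-unit response detection via a binwise rank-sum criterion with
    Simes correction, semantic tuning-curve rank contrasts, Poisson-surprise
    burst detection, and a pre-stimulus spreading-activation test. A
    synthetic-session generator produces trial sequences, reaction times,
    inhomogeneous-Poisson spike trains, and ERP-like traces under
    configurable ground-truth mechanisms so every stage is testable without
    patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
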