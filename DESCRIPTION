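Package: cholinphys
Title: Firing-Pattern, Event-Response and Photometry Analysis for Cholinergic Neurophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cholinergic-neuron physiology experiments:
    autocorrelogram-based firing-pattern statistics (Burst Index, Theta Index,
    relative refractory period) and classification of bursting versus regular
    rhythmic phenotypes; peri-event time histograms with a rank-test based
    detection of event-related activations and inhibitions; optogenetic-tagging
    classification and PCA plus hierarchical-clustering functional cell typing;
    fiber-photometry preprocessing (isosbestic dF/F correction, zero-phase
    Butterworth filtering, baseline z-scoring) and trial-level response
    quantification; cross-regional coupling via normalized cross-correlation,
    transfer entropy on discretized series, and pupil-calcium coupling; in vitro
    current-step metrics; anatomical tracing arithmetic; and seeded synthetic-data
    generators that emulate every statistical structure the analyses assume so the
    whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
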