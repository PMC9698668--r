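Package: topochron
Title: Topochronic Mapping of Functional Transmission Delays from Neuronal Avalanches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-edge functional transmission delays of large-scale
    brain activity from neuronal avalanches detected in source-reconstructed
    electrophysiological time series, and combines them with structural tract
    lengths to obtain per-edge conduction velocities (a "topochronic map").
    Includes avalanche detection on z-scored, thresholded, time-binned rasters;
    branching-parameter analysis for time-bin selection; subject- and
    group-level delay and velocity matrices; time-shuffled avalanche surrogate
    null models; Kolmogorov-Smirnov group comparisons; an edge-wise lesion
    permutation test; a convergence analysis; and a fully synthetic,
    ground-truthed cohort generator (connectomes with fat-tailed tract lengths,
    cascade simulation on delayed networks, lesion-induced slowdowns) so that
    every stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
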