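Package: oscnet
Title: Frequency-Resolved Phase-Synchronization Connectomes from Oscillatory Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and analysing large-scale oscillatory
    phase-synchronization networks from trial-epoched, parcel-level
    electrophysiological time series. Implements a complex Morlet filterbank,
    pooled and single-trial connectome estimation with the imaginary
    phase-locking value (iPLV), edge-level group statistics with
    false-positive pruning and simulated-null density thresholds,
    graph-theoretic summaries (edge density, graph strength, centralities,
    subsystem contrasts), leakage-aware hyperedge bundling with shared versus
    condition-specific subgraph classification, and single-trial random-forest
    decoding of task conditions. A synthetic-data generator with planted
    phase-coupled edges, zero-lag leakage mixing and behavioural tables makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
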