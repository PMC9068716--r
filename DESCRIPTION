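Package: hyperbrain
Title: Dual-Brain EEG Phase Synchronization and Hyperbrain Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-person ("hyperscanning") EEG
    recordings. Estimates undirected phase synchronization with the
    corrected imaginary phase-locking value (ciPLV) and directed
    synchronization with the phase slope index (PSI), performs
    network-based cluster permutation inference on inter- and intra-brain
    edge sets, builds z-scored thresholded hyperbrain graphs over both
    participants' channels, and computes graph-theoretical summaries
    (global/local efficiency, modularity against the two-brain partition,
    degree assortativity, rich-club structure, directed flow between
    leader and follower). Includes a coupled-oscillator dyad simulator
    with condition-dependent and time-delayed inter-brain coupling, a
    behavioral leadership pipeline, and EDF/CSV/GraphML input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
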