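Package: mstnet
Title: Minimum Spanning Tree Analysis of EEG Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying motor-imagery EEG brain
    networks. Preprocesses multichannel recordings (Butterworth band-pass
    and notch filtering, decimation, exponential moving standardization,
    epoching), estimates multitaper power spectra with band power, relative
    power, and frontal alpha asymmetry, computes phase-lag index (PLI) and
    weighted phase-lag index (WPLI) connectivity matrices, builds
    maximum-weight spanning trees and derives edge-, node-, and
    network-level graph metrics (degree, betweenness centrality, diameter,
    leaf fraction, tree hierarchy, global functional connectivity, graph
    edit distance), and compares conditions with network-based statistics
    (NBS) permutation tests plus Wilcoxon signed-rank tests under false
    discovery rate control. Includes a synthetic cohort generator of
    phase-coupled oscillators with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
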