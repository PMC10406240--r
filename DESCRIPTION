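Package: eegalign
Title: Eigenvector Alignment Analysis of EEG Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust assessment of EEG sensor-space functional connectivity.
    Estimates band-averaged imaginary coherency (iCOH) and band-limited
    correlation networks from multi-trial EEG epochs, embeds channels in the
    space of the connectivity matrix's dominant eigenvectors to obtain
    pairwise eigenvector-alignment angles, tests alignments against
    distribution-preserving randomized null ensembles with Welch t-tests and
    Benjamini-Hochberg false-discovery-rate control, filters findings for
    cross-band consistency, and quantifies robustness of the alignment
    pattern to targeted erasure or creation of connections. Includes a
    synthetic generator of multichannel oscillatory epochs with lagged
    coupling, volume-conduction-like instantaneous mixing and sensor noise,
    plus sensor-layout utilities and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
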