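Package: signedlogic
Title: Logical Modelling and Steady-State Analysis of Signed Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing signed directed networks of
    gene and protein interactions in the style of logical (Boolean) models of
    signalling, exemplified by DNA-damage/p53 models with apoptosis and
    senescence outputs. Provides readers and writers for a tab-separated signed
    edge-list dialect, structural analytics (layers around a centre node,
    connectivity degrees, two-step feedback loops, input/output link censuses),
    the six-class dependency matrix built from positive and negative elementary
    paths and negative feedback loops, in-silico knockout screening with
    dependency-matrix differencing, three-valued logical steady-state (LSS)
    propagation with an exhaustive small-network oracle, and a concordance
    statistic comparing discretized model predictions with discretized
    expression fold changes. Synthetic generators for random signed networks
    and planted-signal expression tables make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
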