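Package: fbmnet
Title: Fundamental Boolean Model Networks for Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and data-driven inference of fundamental Boolean
    networks (FBNs), a Boolean formalism for gene regulatory networks with
    separate activation, inhibition and protein-decay channels. Provides
    decomposition of conventional Boolean rules into fundamental activation
    and inhibition functions, a synchronous dynamical engine with decay
    windows and per-rule confidence gates, attractor enumeration, an
    orchard-cube measure database (confidence, counter-confidence, support,
    conditional causality, entropy and mutual information over prefix trees
    of candidate regulator sets), rule mining from the cube, reconstruction
    of Boolean time series and reconstruction scoring (error, accuracy,
    perfect-match and mismatch rates). Reads and writes BoolNet-style
    "targets, factors" network text, a readable FBN rule dialect, tabular
    Boolean time series, and DOT/GraphML graph exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
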