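Package: glogsim
Title: Generalized Logical Simulation of Cellular Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamical simulation of cellular signaling networks with a
    generalized logical model: continuous activity levels in [0,1], signed and
    weighted directed interactions, a global degradation rate, and
    time-scheduled extracellular perturbations delivered through a virtual
    input node. Includes stable-state detection, downsampling of simulated
    time courses to measurement time points, Spearman goodness-of-fit against
    measured protein time courses, initial-value sensitivity sweeps,
    edge-weight robustness analysis, random-network and pseudo-measurement
    generators, and command-line entry points for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
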