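Package: chemoscape
Title: Chemostat Resource Competition Under Metabolic Trade-Offs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and strategy-evaluation toolkit for chemostat
    resource-competition models with exact metabolic trade-offs. Provides five
    metabolic models (substitutable nutrients, substitutable nutrients with a
    serial assimilation step, essential nutrients, nutrient interconversion,
    and intermediate secretion) behind a common growth/impact contract,
    adaptive chemostat and linked-chemostat dynamics, the geometry of chemical
    space (growth contours, flux-balance curves, supply lines, maximizing
    strategies and maximal growth contours with class labels), and
    evolutionary procedures (rule of invasion, environment-dependent fitness
    landscapes, chains of invasion, greedy opportunist assembly, and pairwise
    invasion graphs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
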