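Package: myoregen
Title: Agent-Based Simulation of Skeletal Muscle Damage and Regeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A coupled mechanobiological simulator of skeletal muscle damage
    and regeneration on a 2D fiber-bundle cross-section. Combines a
    closed-form hyperelastic/active-contraction evaluator that ranks
    strain across fibers under eccentric stretch with an hourly-tick
    agent-based model of neutrophils, M1/M2 macrophages, satellite cells,
    myoblasts, fibroblasts and five secreted factors (IGF-1, TNF-alpha,
    TGF-beta, HGF, IL-6). Supports repeated injury-regeneration cycles to
    contrast typically developing and cerebral palsy muscle milieus, plus
    damage, satellite-cell and material-parameter sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
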