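Package: coinvade
Title: Community Stability from Single- and Multi-Species Invasion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for invasion-criterion analyses of microbial community
    stability. Enumerates single- and multi-species (co-)invasion assay
    designs over a species pool, simulates batch-culture colony-count data
    under a generalized Lotka-Volterra model with a plate-count observation
    model, computes relative invader growth rates from CFU counts
    (Malthusian parameters with explicit below-detection policies), and
    classifies community stability with one-sample tests under false
    discovery rate control, including single- versus co-invasion
    comparisons by rank correlation, factorial linear models, and
    within-treatment contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
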