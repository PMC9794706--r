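Package: richscape
Title: Elevational and Spatial Richness Patterns of Threatened Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing species-richness patterns of threatened
    plants along elevational and spatial gradients: range-interpolation
    richness over 100-m elevational bands, a Monte-Carlo mid-domain-effect
    null model with an analytic expectation, 20-km grid richness with greedy
    complementarity hotspot selection, raster-derived impact variables
    (climate means, elevational relief, human-footprint change),
    negative-binomial GLM all-subsets model selection with VIF screening and
    adjusted explained deviance, and a standardized path model. Includes a
    synthetic-landscape generator with stored ground truth so the whole
    pipeline can be exercised end-to-end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
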