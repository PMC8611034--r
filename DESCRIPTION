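Package: coolcity
Title: Counterfactual Land-Cover Contrasts of Urban Land Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Estimates how much cooler urban trees and treeless green spaces
    are than continuous urban fabric from satellite land surface temperature
    (LST) scenes. Each scene is fitted with a penalized additive model (a 2-D
    tensor-product smooth over coordinates plus thin-plate splines for
    elevation, north-facing slope fraction and per-class land-cover
    fractions); the cooling contrast is the difference between counterfactual
    predictions at 100% cover of two classes, with delta-method standard
    errors. Contrasts are related to background air temperature with a robust
    (re-descending M-estimator) local regression whose endpoint gives the
    hot-extreme cooling, summarised by season and synthesized across cities
    via smooth spatial trend surfaces and group means. Per-class
    evapotranspiration and albedo signatures are attributed by linear
    unmixing of coarse rasters on sub-pixel fractions. A synthetic-city
    generator with fully known ground truth makes every stage testable by
    parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
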