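Package: vertebrotwin
Title: Twin-Study Heritability of Vertebrobasilar Vessel Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic and environmental determinants of
    vertebrobasilar artery geometry with the classical twin design. Provides
    centerline morphometry for 3D vessel models (discrete Frenet curvature and
    torsion, tortuosity, basilar bend, cross-sectional area and volume,
    vertebral artery dominance), maximum-likelihood ACE/AE/CE/E variance
    component models for twin pairs with covariate-adjusted means, saturated
    model comparison, AIC/BIC model selection, profile-likelihood confidence
    intervals and likelihood-ratio tests, a parametric generator of synthetic
    twin cohorts with ACE-structured phenotypes and matching Y-shaped
    vertebrobasilar networks, and a reproducible simulate-measure-model
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
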