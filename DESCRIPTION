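Package: rseiq
Title: Remote Sensing Ecological Index Construction and Geodetector
    Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds the remote sensing ecological index (RSEI) from the four
    classic indicators (greenness, wetness, heat, dryness) by principal
    component analysis, grades it into five ecological-quality classes,
    detects multi-epoch change, and attributes the spatial differentiation of
    ecological quality to natural and social covariates with the four
    Geodetector statistics (factor q, interaction typing, risk t-tests,
    ecological F). Includes band algebra for tasseled-cap wetness, soil and
    built-up indices, MNDWI water masking and dimidiate-pixel fractional
    vegetation cover, plain-text raster I/O with nodata handling, exact
    Fisher-Jenks natural-breaks discretization, and a synthetic-landscape
    generator with analytically known q values for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mgcv,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
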