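Package: dietmix
Title: Mixture-Design Cost-Effectiveness Analysis for Mass-Rearing Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constrained three-component mixture experiments used to
    optimize insect mass-rearing diets. Fits Scheffe polynomial response
    surfaces on the pseudo-component scale with a sequential model-selection
    ladder (Type I sums of squares, lack of fit, PRESS and predicted R-squared,
    adequate precision), hierarchical backward elimination, and the standard
    regression influence diagnostics (externally studentized residuals, Cook's
    distance, DFFITS, DFBETAS, Box-Cox profiles) with an outlier-exclusion
    workflow. A linear ingredient-cost model converts blend proportions into
    per-ton and annual costs and savings, and a grid-based overlay optimizer
    locates the region of the design space in which all biological responses
    stay within confidence limits of the standard blend while ingredient cost
    is minimized. Includes a seedable synthetic run-table generator for
    validating every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
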