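Package: watact
Title: Water Activity Prediction in Aqueous Sugar and Polyol Solutions
    from Theoretical Molecular Descriptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting the water activity of binary aqueous
    solutions of sugars and polyols from the molecular structure of the
    solute.  Implements a minimal SMILES parser and hydrogen-depleted
    molecular graphs for the relevant chemistry (C/O skeletons, branches,
    rings); computes the information index on atomic composition (I_AC),
    the first Zagreb index (Z1) and their sum, the global information
    index (G); estimates the Norrish constant k_N from activity data by
    least squares; fits five quantitative structure-property (QSPR) model
    forms linking k_N to the descriptors; and reconstructs water-activity
    curves for new solutes.  Ships the literature reference values for
    eight sugars and polyols together with a synthetic activity-data
    generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
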