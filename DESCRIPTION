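Package: eclipser
Title: Elimination of Cells Lying in Patterns Similar to Endogeneity for
    Multicolor Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated gating of response-specific cells in multicolor flow
    cytometry cohorts. Builds a simultaneous component (multiset PCA) model of
    control-group cell variability, projects responder cells into it, flags
    cells the control model cannot explain via squared-prediction-error control
    limits, removes responder cells overlapping control marker expression with
    a Difference-between-Densities filter based on automatic-bandwidth kernel
    density estimates, refits a response-specific component model on the
    surviving cells, and stratifies responders by hierarchical clustering of
    their response-cell density distributions. Includes a synthetic cytometry
    cohort generator with ground-truth labels, bootstrap-based component-number
    validation by principal angles between loading subspaces, plotting helpers,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    ggplot2,
    rlang,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'preprocess.R'
    'control_model.R'
    'density.R'
    'response_filter.R'
    'eclipse_model.R'
    'eclipser-package.R'
    'io.R'
    'plots.R'
    'synthetic.R'
    'validation.R'
    'pipeline.R'
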