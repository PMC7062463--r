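Package: stclust
Title: Spike-Triggered Clustering of Nonlinear Receptive-Field Subunits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of nonlinear receptive-field
    subunits (two-stage linear-nonlinear cascade models with Poisson
    spiking) by soft clustering of spike-triggered stimuli. Includes the
    locally normalized L1 proximal regularizer for spatially compact
    subunits, hierarchical (split-based) and population (shared-bank)
    variants of the estimator, construction of receptive-field null
    stimuli under display and pixel-variance constraints, a two-layer
    cone-to-bipolar-to-ganglion-cell response simulator for ground-truth
    validation, and cross-validated model selection with PSTH-based
    prediction accuracy and subunit-geometry analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
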