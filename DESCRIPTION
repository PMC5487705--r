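Package: psfield
Title: Spatial Analysis of Plant Breeding Field Trials with Two-Dimensional P-Splines
Version: 0.1.0
Authors@R: person("Field", "Trials Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-trial spatial analysis of plant-breeding field experiments
    using a two-dimensional P-spline surface with anisotropic smoothing.  The
    smooth field trend is decomposed PS-ANOVA style into linear terms, two main
    smooth trends, two linear-by-smooth interactions and a smooth-by-smooth
    interaction, each with its own smoothing parameter estimated by REML via
    effective-dimension fixed-point updates.  Provides generalized heritability
    based on the genotypic effective dimension, nugget-residual variograms,
    fitted-surface prediction on fine grids, model-comparison metrics against a
    non-spatial baseline, and a simulator for partially replicated (p-rep)
    trial designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
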