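Package: affrf
Title: Affine Gaussian Derivative Models of Visual Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models orientation selectivity of visual neurons in the primary
    visual cortex with affine Gaussian derivative receptive fields. Provides
    anisotropic Gaussian kernels and their scale-normalized directional
    derivatives (spatial and spatio-temporal), closed-form and numerically
    computed orientation-tuning curves for simple cells of derivative orders
    one to four and for energy-model complex cells, the circular resultant
    statistic of a tuning curve with closed forms and adaptive quadrature,
    population simulations of resultant histograms over log-uniform
    distributions of receptive-field elongation, nonlinear least-squares
    estimation of elongation from measured tuning curves, and synthetic
    pinwheel orientation-preference maps with per-site eccentricity,
    orientation-homogeneity and selectivity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
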