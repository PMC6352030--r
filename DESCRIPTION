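Package: odkinetics
Title: Mass-Transfer Kinetics of Osmotic Dehydration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing mass transfer during osmotic dehydration of
    plant tissue. Computes dry-basis water content, solid gain, water loss,
    true water loss (water loss corrected for concurrent solute uptake) and
    the dehydration-to-impregnation ratio from raw mass and dry-matter
    measurements; fits Peleg, Kelvin-Voigt and Burgers kinetic models by
    bounded nonlinear least squares with four goodness-of-fit statistics
    (R2, reduced chi-squared, RMSE and the coefficient of residual
    variation); runs two-factor ANOVA with Tukey HSD homogeneous letter
    groups and Pearson correlation of water activity against water content;
    and simulates complete dehydration studies from known kinetic ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
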