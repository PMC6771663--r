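Package: nestdensity
Title: Orang-Utan Density Estimation from Line-Transect Nest Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Standing-crop nest-count analysis for great-ape surveys.
    Implements binned line-transect distance sampling with uniform,
    half-normal and hazard-rate detection keys and series adjustments,
    AIC model selection with chi-square goodness of fit, effective strip
    width, conversion of nest density to orang-utan density via nest
    production, decay and builder-proportion parameters, factorial
    parameter-sensitivity grids, habitat comparisons (ANOVA, Tukey HSD,
    Shapiro-Wilk, Bartlett), and AICc-based all-subsets linear modelling
    with collinearity screening and full model averaging. Includes a
    survey simulator with known truth for validating every stage, and a
    bundled per-transect dataset from a logged-forest/oil-palm mosaic in
    Sabah, Borneo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
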