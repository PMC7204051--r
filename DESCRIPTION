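Package: tractlife
Title: Small-Area Life Expectancy and Spatial Durbin Error Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates census-tract life expectancy at birth from abridged
    mortality and population tables using the adjusted Chiang II life table
    with a closed-form variance, screens estimates with reliability criteria
    (total deaths, person-years, standard error), builds queen-contiguity
    row-standardized spatial weights, and relates life expectancy to
    social-determinant covariates through a spatial Durbin error model fitted
    by concentrated maximum likelihood, with multicollinearity screening,
    global Moran's I residual diagnostics, likelihood-ratio and AIC model
    comparison, and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
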