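Package: thyrostasis
Title: Structure Parameters and Feedback Modelling of Thyroid Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculators for structure parameters of thyroid homeostasis
    (SPINA-GT, SPINA-GD, SPINA-GTS, Jostel's TSH index, the Thyrotroph T4
    Sensitivity Index, hormone ratios and a repeated-measures repeatability
    statistic), together with the nonlinear pituitary-thyroid feedback model
    the parameters derive from. The model couples Michaelis-Menten hormone
    secretion, plasma protein binding and noncompetitive divisive inhibition
    of thyrotropin release; the package solves its equilibrium, simulates
    day-scale dynamics such as thyrotropic adaptation in critical illness,
    generates pulsatile-circadian TSH time series, constructs a bivariate
    (kite-shaped) TSH-FT4 reference region with homeostatic classification
    of lab panels, and produces synthetic cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
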