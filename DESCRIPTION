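Package: nichegradient
Title: Highest-Probability Intervals and Truncation Analysis on
    Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests the environmental center-periphery (abundant-center)
    hypothesis one environmental gradient at a time. From raw species
    occurrence values on a gradient the package builds a histogram with
    exact Clopper-Pearson binomial confidence intervals under Bonferroni
    adjustment, selects a polynomial degree from the significantly
    different bins, fits a polynomial logistic regression as a continuous
    occurrence-probability curve, extracts the 25% highest-probability
    interval around the mode, computes the relative distance of that
    interval from the gradient midpoint, and classifies whether symmetry
    around the mode is attainable given the variable's natural
    mathematical domain (e.g., precipitation cannot be negative). A
    synthetic occurrence-table generator with known ground truth makes
    the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
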