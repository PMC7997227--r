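Package: diaguncert
Title: Uncertainty of Diagnostic Accuracy Measures for Binormal Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form diagnostic accuracy measures (sensitivity,
    specificity, predictive values, likelihood ratios, diagnostic odds
    ratio, Youden's index, Euclidean distance, concordance probability
    and overall diagnostic accuracy) for a screening or diagnostic test
    whose measurand is normally distributed in the diseased and the
    non-diseased population, together with first-order (GUM-style)
    propagation of measurement and sampling uncertainty to each measure.
    Provides Welch-Satterthwaite effective degrees of freedom, Student-t
    expanded uncertainties and confidence intervals, Agresti-Coull
    prevalence uncertainty, sweep tables and plots versus diagnostic
    threshold, measurement uncertainty and sample size, Monte-Carlo and
    parametric-bootstrap validation of the analytic propagation, and a
    command-line interface over summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
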