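Package: vdrct
Title: Design and Analysis Models for Vitamin D Randomized Controlled Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models for designing and analysing randomized controlled trials
    of vitamin D supplementation against cancer incidence. Implements a
    power-law serum 25-hydroxyvitamin D to odds-ratio dose-response curve, a
    baseline-plus-dose to achieved-concentration status-response model (a
    calibration table and a smooth parametric backend), decile-stratified
    expected cancer case computation, Woolf odds-ratio confidence intervals
    and p-values on (possibly fractional) 2x2 expected counts, a
    required-sample-size solver based on the upper confidence bound crossing
    unity, and an individual-level Monte Carlo trial simulator for empirical
    power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
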