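Package: resistlab
Title: Insecticide Resistance Bioassays: Probit Analysis, Inheritance and
    Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of quantal insecticide bioassays for resistance
    characterization: maximum-likelihood probit concentration-mortality
    fitting on log10 dose with lethal-concentration estimation by the
    delta method, resistance ratios with lethal-dose-ratio confidence
    intervals, likelihood-ratio tests of equality and parallelism between
    lines, Stone and Bourguet degrees of dominance, the backcross
    chi-square test of monogenic inheritance, and survival analysis of
    resistance stability across generations. A seeded genetic simulator
    generates bioassays, reciprocal crosses, backcrosses and
    multi-generation cage populations under one-locus or polygenic
    tolerance architectures with an optional fitness cost, providing data
    with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mvtnorm,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
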