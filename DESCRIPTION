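Package: nonpaternity
Title: Individual-Based Simulation of Nonpaternity and Half-Sibling
    Biomarkers of Extramarital Sex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic individual-based (Monte Carlo) simulation of
    partnering, conception, gestation, birth and death in a female
    population, designed for Sub-Saharan African demographic settings.
    Computes four objective population measures of extramarital sex from
    birth registries and partnership logs: the nonpaternity ratio, the
    age-specific nonpaternity ratio, the extramarital partnership ratio,
    and the half-siblings ratio. Includes experiment runners that assess
    the reliability of these measures as behavioural biomarkers via
    Pearson correlations with Fisher z confidence intervals, historical
    back-casting scenarios with time-varying nonmarital sex rates, and a
    sweep over the marital share of coital acts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
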