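Package: oppsel
Title: Sex-Specific Selection and Opportunity for Selection in Competitive Mating Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing competitive mating assays of the kind used to
    measure diet-induced selection in flour beetles: selection coefficients
    against stressed individuals with bootstrap confidence intervals and
    permutation tests for sex differences, the opportunity for selection
    (variance in mean-standardised reproductive success), a multiplicative
    decomposition of male reproductive success into genetic mating success,
    partner fecundity and paternity share, quasi-Poisson and Gaussian
    treatment contrasts with Benjamini-Hochberg adjustment, Yates-corrected
    chi-squared mortality tests, and a synthetic-data generator that emulates
    the mating-group design so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
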