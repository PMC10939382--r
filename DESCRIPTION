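Package: evorescue
Title: Evolutionary Rescue from Climate Change with Male Indirect
    Genetic Effects on Lay-Date
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic moving-optimum models of avian breeding
    phenology under sustained climate warming, extended with female social
    plasticity to a male partner trait (indirect genetic effects) and
    cross-sex genetic correlations.  Provides closed-form critical rates of
    environmental change, the multivariate response to selection, optimal
    social plasticity and the range over which partner effects aid
    persistence, a generation-by-generation recursion simulator that
    independently verifies the closed forms via bisection on the
    extinction boundary, and Monte Carlo propagation of published
    parameter-estimate uncertainty into densities of the critical rate.
    Ships a species table of variance components and demographic rates for
    common gull, great tit, and song sparrow, and a command-line interface
    for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
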