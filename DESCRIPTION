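Package: agedrift
Title: Genetic Drift and Effective Population Size in Age-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how survivorship curve shape and generation time
    govern the rate of genetic drift in age-structured populations. Builds and
    validates one-year-class life tables (including idealized Type-I, Type-II and
    Type-III survivorship families), constructs normalized Gaussian fecundity
    schedules, computes pace/shape descriptors of ageing (life expectancy,
    Keyfitz entropy, lifespan equality, longevity ratio) and Felsenstein's
    effective population size for overlapping generations, and runs a stochastic
    Leslie-matrix simulator of allele frequency drift and recessive viability
    selection at a single diploid locus with Mendelian mating among newborns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
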