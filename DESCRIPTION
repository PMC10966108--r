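Package: amkin
Title: Genetic Similarity Between Relatives Under Assortative Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genetic consequences of assortative
    mating in extended families. Provides closed-form equilibrium
    expectations for genotypic and polygenic-index correlations between
    relatives (including in-laws), a deterministic generation-by-generation
    recursion for the approach to intergenerational equilibrium, a
    forward-time diploid polygenic simulator with phenotypic assortment
    that emits cohort-like pedigree and polygenic-index tables, pedigree
    kinship coefficients with degree classification, dyadic correlation
    estimation with confidence intervals and theoretical overlays, a
    mother-father-child trio model fitted by full-information maximum
    likelihood with a likelihood-ratio test of intergenerational
    equilibrium, and inference of the equivalent number of generations of
    stable assortment from the U statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
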