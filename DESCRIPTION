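Package: multigen
Title: Multigenerational Breeding-Population Simulation and
    Additive-Dominance G-BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates multi-generation breeding populations derived from
    an F2 base (advancement by self-pollination, random mating, or
    backcrossing), simulates quantitative traits with configurable
    dominance and heritability, fits the additive-dominance G-BLUP model
    by REML, measures linkage disequilibrium decay, and evaluates
    genomic-selection calibration strategies that pool training
    information across generations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
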