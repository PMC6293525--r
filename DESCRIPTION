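Package: ccqg
Title: Quantitative Genetics of Collaborative Cross Mouse Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multiparent recombinant inbred
    mouse populations in the style of the Collaborative Cross (CC).
    Provides a breeding simulator (eight-founder funnel crosses followed
    by sib-mating inbreeding, Haldane crossover model), hidden Markov
    model reconstruction of each line's genome as a probabilistic mosaic
    of founder haplotypes, kinship computation from descent
    probabilities, narrow-sense heritability by maximum-likelihood
    variance components and broad-sense heritability by one-way ANOVA,
    haplotype-dosage QTL scans on weighted line means with permutation
    genome-wide thresholds and LogP-1 support intervals, and rank-based
    gene enrichment of QTL intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
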