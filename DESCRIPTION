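Package: bloomclone
Title: Population Genetics of Clonal and Sexual Diatom Blooms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genetic structure of blooming
    phytoplankton populations sampled repeatedly through time. Implements
    multilocus-genotype statistics for microsatellite fingerprinting data
    (genotypic richness, unbiased expected heterozygosity, the standardized
    index of association with a Monte Carlo permutation test, mating-type
    ratios), population differentiation from allele frequencies (pairwise
    Nei G_ST, principal coordinates analysis, percolation-threshold
    networks, Evanno delta-K post-processing of Bayesian clustering output),
    and a Microsatellite Pool-seq Barcoding (MPB) caller that turns pooled
    amplicon sequences into filtered, normalized allele-frequency tables
    with homoplasy-aware allele naming and recombinant flank detection.
    A forward simulator of clonal versus sexually recombining populations
    with mating types, stepwise microsatellite mutation and read-level
    sequencing error provides a fully synthetic test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
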