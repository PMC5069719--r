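Package: glacialdemog
Title: Population Structure and Glacial Demographic History from mtDNA and
    Microsatellites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the historical demography of a two-population
    coastal species from mitochondrial control-region sequences and
    microsatellite genotypes. Provides haplotype and nucleotide diversity with
    exact variances and rarefied haplotype richness, two-level haploid AMOVA
    (PhiST/FST) with permutation tests including a phylogeographic-structure
    test, Cornuet-Luikart heterozygosity deficit/excess bottleneck tests under
    stepwise and two-phase mutation models, a backward-time coalescent
    simulator over demographic scenario templates (HKY sequence mutation,
    generalized stepwise microsatellite mutation), and Approximate Bayesian
    Computation model choice and parameter estimation between competing
    glacial-history scenarios. A synthetic-data generator emulates the study
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
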