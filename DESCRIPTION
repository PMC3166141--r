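Package: gsipop
Title: Population Genetics of Gametophytic Self-Incompatibility Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating putative self-incompatibility (S-) alleles
    with crossing data and sequence data. Implements phenotype prediction and
    concordance statistics for gametophytic self-incompatibility (GSI)
    crossing designs (contingency chi-square, Fisher exact, segregation
    goodness of fit, diallel analysis); a structured-coalescent simulator of
    S-locus samples contaminated by a recombining duplicated pseudogene, with
    Jukes-Cantor sequence evolution along the resulting marginal genealogies;
    a nonparametric permutation test of recombination based on the decay of
    linkage disequilibrium (r-squared) with distance; and pairwise and
    sliding-window nucleotide diversity with Nei-Gojobori synonymous and
    non-synonymous divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Biostrings,
    optparse
Config/testthat/edition: 3
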