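Package: paraclade
Title: Recombination-Aware Phylogenetics of Multigene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises recurrent gene conversion between
    paralogous loci in a multigene family, as exemplified by the vertebrate
    IFIT1/IFIT1B pair. Provides a forward simulator of gene-family evolution
    along a species tree (HKY85 substitution, duplication, loss,
    pseudogenisation and non-reciprocal conversion tracts with a ground-truth
    event log), codon-aware pairwise and progressive alignment, whole-gene and
    sliding-window percent identity and Nei-Gojobori (1986) synonymous
    divergence, a Bernoulli change-point locator for the identity dichotomy,
    HKY85 maximum-likelihood tree inference with nonparametric bootstrap,
    an information-criterion model-averaged single-breakpoint scan for
    phylogenetic incongruence with a permutation p-value, and classifiers that
    assign genes to ortholog clades, call conversion events from 5'/3' tree
    discordance, and flag pseudogenes by frameshift and nonsense mutations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ggplot2
Config/testthat/edition: 3
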