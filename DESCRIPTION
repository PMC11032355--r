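Package: stasis16S
Title: Evolutionary Stasis Analysis of 16S rRNA at Genus Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of 16S rRNA divergence against genome-wide
    divergence within bacterial genera. Computes fragment-based average
    nucleotide identity (ANI) and concatenated single-copy-ortholog maximum
    likelihood distances, flags species pairs that share a near-identical 16S
    rRNA variant despite being well-separated at the genome level (candidate
    horizontal transfers), fits and selects rate-accumulation models
    (zero-intercept linear, second-order polynomial, logarithmic), and
    catalogues intragenomic 16S variant mixtures with phylogenetic-randomness
    and metadata-enrichment tests. A forward genus-evolution simulator
    (Yule tree, Jukes-Cantor substitution, intragenomic gene conversion,
    inter-lineage rRNA transfer, and a vertebrate 18S/mitochondrial-16S mode)
    makes every stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
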