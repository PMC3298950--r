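Package: fasterz
Title: Z-Versus-Autosome Polymorphism and Divergence Analysis for
    Multilocus Haplotype Data
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Tools for contrasting Z-linked and autosomal variation in
    multilocus phased haplotype data from birds and other female-heterogametic
    taxa. Implements per-locus diversity statistics (Watterson's theta,
    nucleotide diversity, Tajima's D), classification of sites between species
    pairs into exclusive, shared and fixed categories, Z:autosome ratio tests
    against the 0.75 neutral expectation, multilocus Hudson-Kreitman-Aguade
    tests with coalescent-simulated null distributions, AMOVA and Phi-ST
    population structure with permutation tests, Hudson-Kaplan four-gamete
    recombination filtering, and a structured-coalescent
    isolation-with-migration simulator with infinite-sites mutation,
    Z-chromosome inheritance scaling and hemizygous females for generating
    synthetic haplotype datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
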