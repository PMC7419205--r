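Package: paleodup
Title: Detection and Dating of Ancient Whole-Genome Duplications from
    Synteny and Ks Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the polyploid history of a plant
    genome from gene order and coding sequence alone: collinear
    (syntenic) block detection by dynamic-programming chaining of
    homologous anchor pairs, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor multiple-hit correction, per-block median Ks
    distributions with kernel density estimation and multi-Gaussian
    peak fitting, cross-lineage evolutionary-rate correction and
    molecular dating of whole-genome duplication events, long terminal
    repeat (LTR) retrotransposon insertion-time estimation from 5'/3'
    LTR divergence, and k-mer based genome-size estimation. A
    synthetic-evolution simulator generates genomes descended from an
    ancestor through whole-genome duplications with stochastic gene
    loss, codon sequences with controlled synonymous divergence, LTR
    pairs diverged under Jukes-Cantor, and error-free reads, so every
    stage of the pipeline is testable against known truth without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
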