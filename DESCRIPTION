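Package: hexfrac
Title: Subgenome Orthology and Biased Fractionation After Whole-Genome Triplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic inference of subgenome orthology and biased
    fractionation in genomes descending from an ancient hexaploidy
    (whole-genome triplication). Fits nested continuous-time Markov models of
    homoeologous gene loss over a species tree, resolves per-locus subgenome
    orthology with a hidden Markov model across syntenic "pillars", selects
    among gene-loss and subgenome-arrival models by likelihood-ratio tests,
    assigns genes to least-, intermediate- and most-fractionated subgenomes,
    extracts subgenome-assigned intergenic regions (SAIRs), and compares
    repetitive-element densities between subgenomes with a placement
    randomization test. Includes a synthetic-data generator with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    ape,
    Matrix,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    withr,
    jsonlite
Config/testthat/edition: 3
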