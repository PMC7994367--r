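Package: oligosom
Title: Genome Signatures, Batch-Learning Self-Organizing Maps and CpG
    Suppression Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics of large genomes from short
    oligonucleotide composition. Cuts genome assemblies into fixed-length
    sliding windows, summarises each window as a strand-invariant
    degenerate k-mer ("genome signature") vector, clusters windows on a
    PCA-initialised batch-learning self-organizing map (BLSOM), and turns
    the trained map into species territories, rank-based oligonucleotide
    contribution heat maps, satellite-territory and shared-node reports.
    Companion metrics quantify CpG suppression (CG observed/expected odds
    ratio, CG/GC ratio) genome-wide and along chromosomes in sliding
    windows, with quadratic trend fits and peak calls. A first-order
    Markov synthetic genome generator with known signatures, CG
    suppression levels, chromosomal CG gradients and CG-rich repeat
    blocks makes the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
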