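Package: kspect
Title: K-mer Counting with Cascading Bloom Filters and Count-Spectrum
    Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Memory-efficient counting of k-mers and spaced seeds from
    sequencing reads using a cascade of Bloom filters and counting Bloom
    filters with minimum/maximum occurrence thresholds, simultaneous
    extraction of per-read k-mer depth (the number of reads containing each
    k-mer), and analysis of k-mer count histograms by fitting a flexible
    mixture model (error, heterozygous and homozygous components drawn from
    a pool of distributions) with differential evolution followed by BFGS
    refinement. The fitted model yields genome-level summaries (k-mer
    coverage, heterozygosity, error and robust k-mer rates, genome size)
    and per-k-mer posterior classification. Includes a synthetic diploid
    genome and read simulator so every analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
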