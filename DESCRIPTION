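Package: begsim
Title: Forward-in-Time Wright-Fisher Simulation with a Backward Event Graph
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Diploid Wright-Fisher forward simulation of non-neutral mutations
    with fitness-proportional sampling, finite-sites mutation and multi-breakpoint
    recombination, plus an ancestry-based algorithm that reconstructs the
    observable history of all surviving lineages as a Backward Event Graph (BEG)
    and places neutral mutations a posteriori, equivalently to simulating them
    forward in time. Includes demography (size changes, bottlenecks, exponential
    growth), coalescent summary statistics (segregating sites, nucleotide
    diversity, haplotype count, site frequency spectrum), ms-format input/output,
    packed-bit haplotype matrices, a validation harness against coalescent closed
    forms, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
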