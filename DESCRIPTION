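Package: canidnm
Title: De Novo Mutation Analysis for Multi-Breed Dog Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for germline de novo mutation (DNM) analysis in
    parent-offspring trios, built around multi-breed dog pedigrees. Implements
    the trio DNM filter cascade with read-level post-checks, callable-site and
    sex/ploidy-scaled callable-size accounting, bootstrap mutation-rate
    estimation (genome-wide, regional, and nucleotide-composition corrected),
    identity-link Poisson regression of phased mutation counts on parental age
    (maximum likelihood and Metropolis MCMC), mutational-spectrum comparison
    across cohorts, sibling-shared mutation and hypermutation analysis,
    crossover breakpoint detection from phased haplotype tracks, and a
    branch-ratio solver that dates the loss of PRDM9-directed recombination
    from paired phylogenies. A synthetic-cohort generator reproduces the
    statistical structure the analysis assumes so that every stage is testable
    without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
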