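Package: mutacc
Title: Mutation-Accumulation Analysis of Bacterial Conditional Hypermutators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bacterial mutation-accumulation (MA) experiments with
    deficient DNA repair: pyrimidine-centric replication-stranded triplet
    contexts, variant identification and back-tracing from per-position count
    tables, maximum-likelihood mutation rates with exact Poisson and binomial
    intervals, hierarchical Bayesian estimation of stranded-triplet rates,
    mathematical models of mismatch-repair saturation, proofreading bias
    amplification and two-subclass aggregation, entropy/KL dispersion
    statistics, Luria-Delbruck fluctuation-assay estimation, and synthetic-data
    generators for every input format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    rjags,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
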