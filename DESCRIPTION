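Package: homeoExpress
Title: Homeologue Expression Patterns and Mutation Load in Allopolyploids
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the two subgenomes of an allopolyploid
    diverge from, and converge towards, their parental species at the
    transcriptome level. Implements classification of total and
    homeologue-specific expression patterns (no-difference, intermediate,
    legacy, reverse, compensatory drift, dominance, transgressive),
    cis/trans regulatory decomposition by regression of the subgenome
    expression log-ratio on the parental log-ratio, similarity, dominance
    and convergence indices with their sign and correlation tests, a
    maximum-likelihood beta-binomial model of the placement of deleterious
    and synonymous mutations between homeologues with hierarchical
    likelihood-ratio model selection and bootstrap confidence intervals,
    and the association test between mutation-load bias and homeologue
    expression bias. A negative-binomial synthetic-data generator with
    exported ground truth supports validation of every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
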