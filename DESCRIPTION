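Package: unguardedX
Title: Sex-Linked Mutation Load and the Unguarded X Hypothesis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic population-genetic models of the sex difference
    in survival and longevity generated by hemizygous expression of
    partially recessive deleterious mutations on X or Z chromosomes at
    mutation-selection balance (the "unguarded X" hypothesis). Provides
    closed-form per-locus equilibrium frequencies and genome-wide
    multiplicative loads, Taylor-series ratio approximations and their
    sex-differential, sex-limited, and dosage-compensation variants,
    X- and Z-linked deleterious mutation budgets under sex-biased mutation,
    named taxon scenarios and parameter sweeps, an exact two-sex
    allele-frequency recursion used as a brute-force oracle for every
    approximation, generators for synthetic locus collections and mock
    tables of sex-biased mutation-rate estimates, and a curation pipeline
    for published male-to-female mutation-rate ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
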