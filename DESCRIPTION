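Package: linksim
Title: Two-Point Parametric Linkage Analysis and Null-Trait False-Positive
    Simulation on Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact two-point parametric linkage analysis on loop-free
    extended pedigrees via the Elston-Stewart peeling algorithm over joint
    trait-marker diplotypes, with LOD scores at fixed or maximized
    recombination fraction. Includes a full simulation laboratory for
    family-wise type-I-error studies: generation of multi-generation
    pedigrees, gene-dropped biallelic markers with optional founder-haplotype
    linkage disequilibrium, polygenic quantitative traits with configurable
    heritability and age trend, founder-quantile dichotomization, purely
    random affection status, founders-only minor-allele-frequency estimation
    with a monomorphic floor, and replicate-level accounting of
    genome-wide-significant false positives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
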