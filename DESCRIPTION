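Package: trapforge
Title: In Silico Bi-Allelic Targeted Trapping of Mouse ES Cell Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates, entirely in silico, the construction of insertion-type
    targeted-trapping vectors (pI_hygGFP) from modular Gateway-adapted
    Intermediate Vectors, the site-specific recombination events (Gateway
    exchange, Cre/loxP, Flp/FRT), PmeI linearization, single-crossover
    insertion targeting with gap repair, and the resulting conditional-allele
    state machine (tm1a, tm1b, tm1c, tm1d, tm2) used to generate bi-allelic
    null mutant mouse embryonic stem cells. Includes splice-trap reading-frame
    phase computation, expression and drug-selection outcome logic, truncation
    product prediction, in-silico long-range PCR genotyping with clone calling
    and screening-efficiency summaries, and seeded synthetic-locus generators
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
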