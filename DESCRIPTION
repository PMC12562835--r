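Package: ystrpedigree
Title: Pedigree-Based Y-STR Mutation and Male Differentiation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of locus-specific Y-chromosomal short tandem repeat
    (Y-STR) mutation rates from pairs of distantly related males sampled from
    two-man pedigrees. Implements parsimony-based minimum-mutation counting
    between haplotype pairs (single-step decomposition of multi-step
    differences, duplication/deletion events at multi-copy loci, microvariant
    handling), per-locus rate estimation mu = x/N with exact Clopper-Pearson
    and Wilson score confidence intervals, Fisher's exact comparison against
    reference studies, meioses-stratified male relative differentiation rates,
    and a seeded stepwise-mutation pedigree simulator with truth logs for
    validation. Includes readers and writers for GeneMapper-style allele
    tables and pair manifests, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
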