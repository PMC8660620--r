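Package: svcohort
Title: Dual-Caller Consensus and Population Screening of Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort-scale structural-variant (SV) analysis toolkit built
    around dual-caller consensus calling. Per-individual call sets from two
    SV callers are reconciled into consensus calls, merged across individuals
    into a non-redundant cohort call set, filtered, and annotated against a
    gene model with simplified location and impact classes. Downstream
    analyses cover group-specific SV screening, presence/absence genotype
    matrices, principal component analysis, exact allele-frequency tests,
    hypergeometric gene-set enrichment, and a three-criterion candidate
    screen for phenotype-associated SVs. A synthetic-cohort simulator with
    planted SVs, breakpoint jitter and caller noise supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
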