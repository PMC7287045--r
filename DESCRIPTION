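Package: SVHarmony
Title: Harmonization and Quality Control of Multi-Caller Structural Variant Call Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-calling harmonization of structural variant (SV) and short tandem
    repeat call sets produced by multiple callers (SpeedSeq/LUMPY, Genome STRiP
    CNVDiscovery and LCNVDiscovery, MELT, HipSTR, wham, manta) on cohorts that
    contain genetic replicates (monozygotic twins, fibroblast-iPSC pairs).
    Implements replication-rate estimation from replicate pairs, per-caller hard
    filters, graph-based within-caller redundancy collapsing, stitching of
    fragmented copy-number variants, cross-caller unification into a non-redundant
    call set, cohort-level quality control (study batch-effect and Hardy-Weinberg
    chi-squared tests, calls-per-sample diagnostics), comparison against external
    call sets, array intensity rank-sum validation, and linkage-disequilibrium
    tagging with nearby SNPs. A synthetic-data generator emulates multi-caller
    views of a planted truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
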