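Package: svcis
Title: Integrating Somatic Structural Variant Breakpoints with Tumor Gene Expression
Version: 0.9.0
Authors@R:
    person("CBTN", "Analyst", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking somatic structural variant (SSV) breakpoints to
    altered expression of nearby genes across a tumor cohort. Builds gene-by-tumor
    breakpoint predictor matrices (window presence and log2 relative distance to
    the gene start), fits per-gene linear models of expression with tumor-type and
    copy-number covariates, estimates false discovery rates by the
    Storey-Tibshirani formula and by stratified permutation of breakpoint
    profiles, annotates SSVs for topologically associating domain (TAD)
    disruption and candidate enhancer translocation, refines RNA-seq gene-fusion
    candidates with WGS breakpoint support and expression evidence, analyzes
    correlates of overall SSV burden, and tabulates pathway-level somatic
    alterations under a fixed precedence ordering. A seeded synthetic-cohort
    generator with a ground-truth manifest makes every stage testable without
    access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
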