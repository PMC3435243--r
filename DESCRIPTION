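Package: cnvfam
Title: Family-Based Rare Copy-Number-Variant Discovery and Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for family-based discovery of rare copy-number variants
    (CNVs) in multiplex pedigrees: merging of two CNV callers' segment calls
    by directional or reciprocal overlap with outer-boundary envelopes,
    population-level inference of the normal copy state at common copy-number
    polymorphisms, cohort quality control (excess-call outliers, ancestry
    oval filter), affected-versus-unaffected burden comparison with
    within-family permutation inference, pooled CNV-region association under
    three copy-state models with a family random intercept and a one-sided
    Fisher fallback, a rarity filter chain (uniqueness against unaffecteds
    and controls, segmental-duplication and known-variant exclusion, family
    consistency), pedigree transmission classification with de novo rate
    estimation, and multi-evidence gene prioritization combining
    order-statistics rank fusion, SAGE tag-count fold enrichment and curated
    expression flags.  A seeded synthetic-cohort generator with planted
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
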