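Package: varfunnel
Title: Family-Based Germline Variant Prioritization and Telomere Assay
    Quantification
Version: 0.1.0
Authors@R: person("Variant", "Funnel Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes germline variants in cancer families through a
    staged funnel: caller quality gates, population rarity, pedigree
    co-segregation under an autosomal dominant model, CADD deleteriousness,
    evolutionary conservation (GERP, PhastCons, PhyloP), and a consensus
    vote over ten dbNSFP-style predictors, with a lenient rescue path for
    known cancer genes. Surviving candidates are ranked (never filtered) by
    gene-level intolerance evidence (pLI, missense Z, intolerance
    percentiles) and can be classified with a generic ACMG/AMP evidence
    combiner. Includes quantification of qPCR relative telomere length
    (T/S = 2^-dCt) and ChIP dot-blot enrichment, and a synthetic
    pedigree/variant generator with a planted causal variant plus
    closed-form survivor expectations so the whole cascade is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
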