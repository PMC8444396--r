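Package: comethQTL
Title: Methylation QTL Mapping on CpG Correlation Blocks with
    Cross-Tissue Colocalization
Version: 0.1.0
Authors@R:
    person("comethQTL", "Developers", email = "comethqtl@example.org",
           role = c("aut", "cre"))
Description: Maps cis methylation quantitative trait loci (methQTLs) by
    first grouping neighbouring, co-methylated CpGs into correlation
    blocks via Louvain community detection on a distance-weighted
    correlation graph, then regressing the methylation level of each
    block's tag-CpG (medoid) on SNP dosages within a 500 kb window with
    covariate adjustment. Includes genotype quality control
    (Hardy-Weinberg exact test, missingness, minor-allele frequency),
    Bonferroni-style genome-wide and replication P-value cutoffs,
    lead-SNP selection, cross-tissue classification of methQTLs into
    common, shared and tissue-specific classes via summary-data-based
    Mendelian randomization (SMR) and heterogeneity-in-dependent-
    instruments (HEIDI) tests, annotation enrichment via one-sided
    Fisher tests, and a synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    data.table,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
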