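Package: bsaqtl
Title: Bulked-Segregant QTL-Seq Mapping with Iterative Sliding-Window
    Refinement and F2 Interval Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq bulked-segregant analysis of two sequenced DNA
    bulks: per-bulk SNP indices and the delta-SNP index, simulation-based null
    distributions conditioned on population type, bulk sizes and read depth,
    empirical per-SNP p-values, fixed sliding-window genome scans with
    QTL-interval calling, and a progressive window-refinement procedure that
    narrows candidate regions over significance-filtered SNPs. A validation
    stage provides F2 linkage mapping: EM recombination-fraction estimation,
    Kosambi map construction, Haley-Knott interval mapping with additive and
    dominance estimates, inclusive composite interval mapping with stepwise
    cofactor selection, and permutation-based LOD thresholds. A synthetic-data
    module simulates segregating populations (F2, recombinant inbred lines,
    backcross), two-locus epistatic ordinal traits, phenotype-based bulking and
    read-depth SNP tables, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
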