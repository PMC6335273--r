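Package: sweepHKA
Title: Artificial Selective Sweep Detection in Inbred Line Pairs via
    Fixed/Polymorphic Homogeneity Scans
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects putative artificial selective sweep (PASS) regions
    between two inbred populations genotyped against a common reference.
    Classifies variant sites as fixed or polymorphic per population under a
    per-population call-count retention filter, scans the genome in sliding
    windows with an HKA-style 2x2 homogeneity test (Fisher's exact or Pearson
    chi-square) under Bonferroni family-wise control, and merges directional
    significant windows into PASS regions. Supporting statistics include
    Tajima's D, Weir-Cockerham Fst and fixed-variant density in tiling
    windows. Codon-level effect annotation of fixed variants against a gene
    model yields specific-amino-acid-changed (SAAC) gene sets; interval
    utilities overlap PASS regions with QTL catalogues; and a
    Bayes-regularized paired t-test on TPM-normalized expression integrates
    differential expression into a final candidate gene set. A seeded
    synthetic two-population generator (toy genome, gene models, VCF,
    QTLs, paired counts) exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Genetics, PopulationGenetics, VariantAnnotation, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
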