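Package: cagetc
Title: CAGE Tag Cluster Dynamics: TSS Usage, Switching and Enhancer
    Detection in Time-Course Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of transcription start site (TSS) dynamics from CAGE
    (Cap Analysis of Gene Expression) data in factorial genotype-by-timepoint
    designs, as used to profile PAMP-triggered immunity in Arabidopsis
    seedlings. Provides CTSS handling with G-addition correction,
    neighbor-clustering of CTSSs into tag clusters (TCs), TPM normalization
    and peak calling, hierarchical genomic annotation of TCs, alternative-TSS
    gating by fractional gene contribution, moderated linear-model
    differential expression with empirical-Bayes variance shrinkage,
    trajectory clustering of responsive genes, differential TC usage and
    promoter-switch detection, classification of TSS consequences (protein
    domain disruption, target peptide exclusion, uORF skipping),
    bidirectional enhancer-candidate detection via the Bhattacharyya balance
    score, and promoter scanning for transcription factor binding-site
    enrichment with JASPAR-format matrices. A fully parameterised simulator
    generates genomes, annotations and CAGE libraries with planted ground
    truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
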