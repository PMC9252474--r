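# cagetc — CAGE tag-cluster dynamics

`cagetc` analyses transcription-start-site (TSS) dynamics from CAGE (Cap
Analysis of Gene Expression) data in factorial genotype × timepoint
designs, of the kind used to profile PAMP-triggered immunity (PTI) in
*Arabidopsis* seedlings: wild type and nuclear-exosome mutants (*hen2*,
*rrp4*) sampled minutes after elicitation with the flagellin peptide
flg22. It is aimed at researchers who want to go beyond gene-level
differential expression and ask *where* transcription starts, how start
sites shift during a response, and what those shifts do to the encoded
products.

## What it computes

Starting from per-library CTSS tracks (single-base BED6 files of 5′-end
tag counts), a GFF3 annotation, a genome FASTA and a design table:

1. **CTSS handling** — strand-aware 1-bp correction for the G-addition
   bias of template-switching reverse transcription; support filtering
   (count ≥ 1 in ≥ 3 libraries).
2. **Tag clustering** — neighbor-clustering of same-strand CTSSs within
   20 bp into tag clusters (TCs); per-library quantification; TPM
   normalization by total library tags; peak calling (maximally
   supported base, 5′-most on ties); expression filtering (≥ 1 TPM in
   ≥ 3 libraries).
3. **Hierarchical annotation** — each TC peak gets one category by
   precedence promoter (± 100 bp of an annotated transcript 5′ end) >
   5′ UTR > CDS > intron > 3′ UTR > antisense > intergenic; intragenic
   TCs are assigned to their host gene and gated at ≥ 10 % contribution
   to gene expression in ≥ 3 libraries; primary/alternative and
   major/minor labels; per-gene rank, fractional usage and Simpson
   diversity *D* = 1 − Σ *p*ᵢ² of TC usage.
4. **Differential expression** — a moderated linear model on normalized
   log₂ TPM with the full factorial design `~ genotype * timepoint`:
   per-feature OLS, empirical-Bayes variance shrinkage
   s²ₚₒₛₜ = (d₀·s₀² + d·s²)/(d₀ + d) with the prior moment-matched from
   the observed log-variance distribution, moderated *t* on d₀ + d
   degrees of freedom, BH correction per contrast, calls at
   |log₂FC| ≥ 1 and FDR ≤ 0.05. Responsive genes are clustered into six
   trajectory shapes (hierarchical clustering, complete linkage,
   correlation distance).
5. **Differential TC usage and promoter switches** — per TC,
   Δ = log₂FC(TC) − mean log₂FC of the gene's other TCs, tested with a
   moderated *t* (diffSplice-style); a gene is a *switch gene* when one
   TC goes significantly up and another significantly down in the same
   contrast.
6. **Consequence classification** — alternative TCs are classified as
   domain-disruptive (peak within or downstream of a protein domain,
   mapped from amino-acid to genomic coordinates), target-peptide
   excluding (peak within or downstream of the first 3 × cleavage-site
   coding nucleotides) or uORF-skipping (peak within or downstream of a
   leader uORF); a scanner finds ATG…in-frame-stop uORFs in leaders.
7. **Enhancer candidates** — bidirectionally transcribed loci scored
   with the Bhattacharyya coefficient BC = √(p₁/2) + √(p₂/2) over
   minus-strand-upstream / plus-strand-downstream windows (500 bp,
   BC ≥ 0.95), then filtered for bidirectional signal in ≥ 3 libraries,
   intergenic/intronic midpoint and nuclear chromosome, and tested for
   differential expression.
8. **TF-binding-site enrichment** — JASPAR-format PWMs scanned over
   500-bp promoters anchored on the CAGE TC peak closest to each
   annotated TSS, with a min–max-normalized log-odds score at 70 %
   similarity; per-cluster enrichment ratios against the genome-wide
   promoter background.

A fully parameterised simulator (`simulate_experiment()`) generates a
genome, annotation, side tables, motifs and CAGE libraries with planted
switches, consequence genes, exosome-sensitive transcripts, trajectory
clusters and enhancers — plus a truth table — so the whole pipeline is
testable end to end without any external data.

## Worked example

```r
library(cagetc)

cfg <- simulation_config(seed = 42)   # 1-Mb genome, 200 genes, 24 libraries
res <- run_pipeline(cfg)

s <- res$summary
cat("tag clusters:", s$n_tcs, " genes detected:", s$n_genes_detected, "\n")
#> tag clusters: 300  genes detected: 200
cat("single-TC genes:", s$n_single_tc_genes,
    sprintf("(%.1f%%)", s$pct_single_tc_genes), "\n")
#> single-TC genes: 139 (69.5%)
cat("DEGs t30:", s$degs_per_contrast$t30,
    " switch genes:", s$n_switch_genes, " DTU TCs:", s$n_dtu_tcs, "\n")
#> DEGs t30: 86  switch genes: 30  DTU TCs: 120
cat("enhancer candidates kept:", s$n_enhancers_final, "of",
    s$n_enhancer_candidates, "\n")
#> enhancer candidates kept: 20 of 20

table(res$consequence$consequence[res$consequence$kept])
#>        domain_disruptive                     none target_peptide_excluding
#>                       10                      231                       10
#>            uorf_skipping
#>                       10

res$deg_clusters$label
#> [1] "repressed_early_sustained" "induced_early_sustained"
#> [3] "repressed_transient"       "induced_transient"
#> [5] "induced_late"              "repressed_late"
```

The summary's `recovery` element compares every call against the
simulator's truth table: here all 30 planted promoter switches are
found with no false switch among the 31 unplanted multi-TC genes, all
30 consequence genes are classified correctly, and all 20 planted
enhancers are recovered at precision 1.0. `run_pipeline(cfg, outdir =
"out")` additionally writes the annotated TC table, DE/DTU/switch
tables, an enhancer BED, the TFBS enrichment matrix and a JSON summary.

Individual stages are exported (`read_ctss()`, `apply_g_offset()`,
`filter_ctss()`, `cluster_ctss()`, `quantify_tcs()`, `filter_tcs()`,
`annotate_tcs()`, `assign_and_filter_intragenic()`, `fit_de()`,
`dtu_test()`, `detect_switches()`, `classify_consequences()`,
`scan_bidirectional()`, `filter_candidates()`, `read_jaspar()`,
`pwm_scan()`, `define_promoters()`, `enrichment_matrix()`, …) and work
on real data read from the standard formats.

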