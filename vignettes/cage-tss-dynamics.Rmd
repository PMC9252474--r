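---
title: "Methods: CAGE tag-cluster dynamics, TSS consequences and enhancer detection"
author: "cagetc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAGE tag-cluster dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `cagetc`, in the spirit of the methods sections of the
Bioconductor expression-analysis packages. Nothing here reports an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The setting

CAGE sequences ~30-bp tags anchored at the capped 5′ end of
transcripts, so each mapped 5′ position (a CTSS) marks a transcription
start at base resolution, with a tag count per library. In a
genotype × timepoint design — wild type and the exosome mutants *hen2*
and *rrp4*, sampled 0/10/30 min after flg22 elicitation, in
triplicate — this resolves four questions at once: which genes respond,
which *start sites* respond (alternative promoters), what the shifted
starts do to the product (domains, targeting peptides, uORFs), and
whether divergently transcribed eRNA-like loci mark candidate
enhancers.

## Coordinates

All internal interval arithmetic uses `GRanges` (1-based, closed), the
R/Bioconductor convention. GFF3 is 1-based closed and needs no shift;
BED input/output converts from/to 0-based half-open explicitly.
Transcript coordinates are 1-based, counted 5′→3′ along the spliced
transcript; `tx_to_genome()`/`genome_to_tx()` are exact inverses and
are property-tested against a per-base splice-walk oracle on random
multi-exon transcripts of both strands.

The G-addition correction (`apply_g_offset()`) shifts CTSS positions by
1 bp *in the direction of transcription* (+1 on the plus strand, −1 on
the minus strand), because the spurious templated G is prepended at the
tag 5′ end. Whether the correction in the original tooling was
strand-aware is not documented; the strand-aware form is the
biologically coherent one and is the package default. The simulator
emits already-corrected coordinates, so `run_pipeline()` defaults to
`g_offset_bp = 0`; set it to 1 for raw mapped tracks.

## Tag clustering

- **Support filter:** a CTSS is kept with ≥ 1 count in ≥ 3 libraries
  (three is the smallest group size in a triplicated design).
- **Clustering:** same-strand CTSSs chain while consecutive positions
  are ≤ 20 bp apart (single-linkage along the chromosome, the
  CAGEfightR gap semantics); strands never merge. Implemented on
  `GenomicRanges::reduce()` and verified exactly against a brute-force
  transitive-closure oracle.
- **Quantification and TPM:** a TC's count is the sum of its member
  CTSS counts; TPM divides by the *total* library tags — not only
  clustered tags — times 10⁶. Library sizes are frozen at matrix
  construction and survive all later filtering, so normalization always
  refers to total mapped tags; the unclustered residue is thereby
  accounted for rather than silently renormalized away.
- **Peak:** the member position with maximal pooled count; ties break
  to the 5′-most position in the direction of transcription, for
  determinism.
- **Expression filter:** ≥ 1 TPM in ≥ 3 libraries, boundaries
  inclusive.

## Annotation hierarchy and the contribution gate

Each TC peak receives exactly one category with precedence
promoter > fiveUTR > CDS > intron > threeUTR > antisense > intergenic.
"Promoter" means within ±100 bp of *any* annotated transcript 5′ end on
the same strand. The exact precedence between the 3′ UTR and antisense
is a documented choice (promoter-proximal sense categories outrank
antisense); it is configurable in spirit by annotating with a modified
region list.

Intragenic TCs are assigned to the same-strand gene whose span
(extended by the promoter window) contains the peak; if two gene spans
overlap the peak, the gene whose annotated TSS is nearest wins. The
per-library contribution of a TC is its TPM divided by the summed TPM
of its gene's TCs; a TC enters alternative-TSS analyses iff its
contribution is ≥ 10 % in ≥ 3 libraries (both thresholds inclusive).
Pooled (mean-TPM) contributions drive ranks, fractional usage and the
Simpson diversity D = 1 − Σ pᵢ² (`vegan::diversity`, the complement
form — stated explicitly since "Simpson index" is ambiguous); the
per-library contributions are used only for the gate.

## The moderated linear model

Differential expression is fitted on y = log₂(TPM + 1) with the
full-factorial design `~ genotype * timepoint`. Cells absent from the
design (rrp4 has no 10-min sample) produce identically-zero interaction
columns, which are dropped; any remaining rank deficiency is an error
naming the aliased terms. Per feature, OLS residual variances s² with d
degrees of freedom are shrunk towards a common prior,

s²ₚₒₛₜ = (d₀·s₀² + d·s²) / (d₀ + d),

with (d₀, s₀²) estimated by moment-matching the log-variance
distribution to a scaled F distribution (digamma/trigamma relations;
the trigamma inverse by Newton iteration). Moderated t statistics use
d₀ + d degrees of freedom; p-values are BH-adjusted within each
contrast separately (the family per contrast is a documented choice).
The implementation is self-contained; the test suite cross-checks
coefficients, residual variances, the estimated prior and the moderated
t against limma's `lmFit`/`eBayes` on identical input, and verifies the
z-statistic limit when all residual variances coincide (d₀ → ∞).

**Normalization.** Under fixed sequencing depth, strong one-sided
induction crowds out unchanged transcripts: every flat feature's TPM
drops and naive log-ratios acquire a compositional shift. Count-based
pipelines absorb this with between-sample normalization factors; here
each design cell is aligned on the *modal* per-feature log₂ ratio to
the baseline cell (reference genotype at the earliest timepoint),
estimated as the kernel-density argmax sharpened by three iterations of
local means (±0.5 log₂ window). The mode, unlike the median, stays
anchored on the unchanged mass even when close to half of the features
respond asymmetrically — the regime the planted simulation deliberately
creates (a 200-gene genome with 120 responding genes). Trajectory
clustering reuses the fit's normalized matrix, so cluster shapes are
read on the same scale as the fold-changes.

- **Trajectory clusters:** responsive genes (DE in any time-course
  contrast) are z-scored over the wild-type timepoint means and
  clustered with complete linkage on 1 − Pearson correlation, cut at
  k = 6 (the cut rule is not prescribed by the number of clusters
  alone; k is a parameter). Clusters are labeled induced/repressed and
  early-sustained/late/transient from their mean trajectory: transient
  when the 10-min deviation is at least twice the 30-min deviation,
  late when at most half, sustained otherwise.
- **DTU:** per TC and contrast, Δ = log₂FC(TC) − mean log₂FC of the
  gene's other TCs, with Var(Δ) from the moderated standard errors
  assuming independence across TCs; BH within contrast; reported iff
  FDR ≤ 0.05 and |Δ| ≥ 1 log₂ in at least one time-course contrast.
  The printed "minimum effect size of 2" is ambiguous between linear
  and log₂ units; it is interpreted as a linear fold-change of 2
  (|Δ| ≥ 1 log₂) and is configurable (`dtu_min_effect_log2`).
- **Switches:** a gene is flagged when one TC is significantly up
  (log₂FC ≥ 1, FDR ≤ 0.05) and another significantly down in the same
  contrast; the most extreme pair is reported with both TCs' annotation
  categories.

## Consequence classification

All "within or downstream" rules are evaluated at the TC peak, strand
aware, with the strict convention that a peak exactly at a feature's 5′
genomic edge counts as *within*; one base upstream retains the feature.

- **Domains:** amino acids [aa_start, aa_end] occupy CDS nucleotides
  [3(aa_start − 1) + 1, 3·aa_end], walked through the CDS exon
  structure into genomic segments (segment widths always sum to 3 × the
  amino-acid span). A sense TC is domain-disruptive iff its peak is at
  or downstream of the 5′-most genomic start of any domain of its gene
  — start-of-domain rather than end-of-domain, the more inclusive
  reading, since a transcript starting anywhere past the domain start
  cannot encode the complete domain.
- **Target peptides:** the peptide-coding span is approximated as the
  first 3 × cleavage-site coding nucleotides (ignoring the stop-codon
  subtlety); same within-or-downstream rule.
- **uORFs:** the scanner reports every ATG…in-frame-stop ORF fully
  within the leader, ≥ 6 nt including the stop, ATG-only starts
  (near-cognate starts are out of scope), all overlaps reported. A TC
  skips a uORF iff its peak is at or downstream of the uORF's genomic
  5′ start.

## Enhancer candidates

With pooled strand-specific signal, a midpoint m scores
U = minus-strand tags in [m − w/2, m − 1] and D = plus-strand tags in
[m, m + w/2 − 1] (w = 500 bp), and the Bhattacharyya coefficient
against the ideal 50/50 split is BC = √(p₁/2) + √(p₂/2) with
p = (U, D)/(U + D); BC is 1 iff U = D and √½ ≈ 0.707 for one-sided
signal, so unidirectional promoters can never pass the 0.95 threshold.
The windowing arithmetic (two half-windows around the midpoint) follows
the published bidirectional-clustering approach; runs of passing
midpoints collapse to the maximal-total midpoint (leftmost on ties) and
overlapping windows merge the same way. Filters: both strands nonzero
in the same library in ≥ 3 libraries (the per-library joint reading of
"bidirectional signal in three or more samples"), midpoint in
intergenic or intronic space, nuclear chromosome. Candidate expression
for differential testing is U + D per library, through the same
moderated model.

## Promoter scanning and enrichment

Promoters are the 500 bp immediately upstream (in transcription
direction) of the TC peak closest to each gene's annotated TSS,
truncated and flagged at chromosome edges. PWM counts are normalized
per position with a pseudocount of 0.8 split by the uniform background;
scores are window log-odds sums min–max-normalized by the matrix's
attainable extremes, and a window matches at relative score ≥ 0.70 —
a deliberate, transparent stand-in for FIMO's p-value machinery that
matches the quoted "minimum similarity" semantics. Both strands are
scanned; overlapping matches all count (no greedy masking), matching
the "number of matches" language. Cluster enrichment is mean matches
per promoter in the cluster over the genome-wide promoter mean; zero
backgrounds are flagged rather than divided by.

## The simulator

`simulate_experiment()` defines the package's reference study
conditions: one 1-Mb nuclear chromosome; 200 non-overlapping three-exon
genes (450 + 501 + 390 nt exons, 210-nt leaders, 981-nt CDS) on
alternating strands with ≥ 600-bp intergenic gaps; a 24-library design
(wt/hen2 at 0/10/30 min, rrp4 at 0/30 min, triplicates); 500,000 tags
per library. Planted features: 30 promoter-switch genes, 10 each of
uORF-skipping, domain-disrupting and target-peptide-excluding genes
(one downstream TC each, 30 % baseline share), 10 exosome-sensitive
transcripts (+2 log₂ in hen2/rrp4), 10 genes in each of six trajectory
shapes (late/early-sustained/transient, induced and repressed, ±3 log₂
— effect sizes in the strongly induced range typical of PTI genes), and
20 enhancer loci (16 intergenic, 4 intronic; five flg22-induced, five
exosome-sensitive).

Counts are negative binomial (dispersion φ = 0.1, a typical
biological-replicate value for sequencing counts and consistent with
the overdispersion presumed by count-based DE frameworks): a TC's
library total is NB with mean proportional to gene baseline share
(log-normal, σ = 1) × TC share × 2^trajectory, rescaled so every
library sums to the configured depth — fixed sequencing depth, so
induced transcripts crowd out unchanged ones exactly as in real
libraries, which is what makes the normalization above necessary and
testable. Tags scatter around the TC peak with geometric decay
(ratio 0.6) within ±10 bp, so a planted TC always reconstructs as one
cluster under the 20-bp rule and its peak is recoverable. The minor-TC
share shrinks with gene expression rank (0.3 down to 0.18), mirroring
the observed decline of alternative-TSS usage in highly expressed
genes; all shares stay comfortably above the 10 % gate. Enhancers emit
divergent signal (minus-strand tags centered 25 bp upstream,
plus-strand 25 bp downstream of the midpoint, 50/50 by default, ~50
pooled tags per library before depth scaling). Planted uORF sequences
(ATG + 18 stop-free codons + TAA) and the consensus of the first of
five synthetic 12-bp motifs (planted 60 bp upstream of every
transient-cluster gene's TSS) are physically written into the genome,
so sequence-level scanners find them. The 12-bp width keeps consensus
insertions well separated from background matches at the 70 %
similarity threshold.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: mapping bias and multi-mapping, promoter
shape heterogeneity (all planted TCs share one decay profile),
divergent gene pairs closer than the enhancer window (intergenic gaps
are kept ≥ 600 bp, so stable divergent promoters cannot masquerade as
enhancers), overlapping genes and antisense transcription, organellar
chromosomes (all simulated sequence is nuclear by default), UTR introns
and uORFs spanning splice junctions, and genome-scale gene counts
(planted features are a far larger fraction of this 200-gene genome
than of a real transcriptome).

## Degenerate inputs and determinism

Empty CTSS files warn and yield zero columns; libraries with zero total
tags get TPM 0 with a warning; genes with zero expression drop their
TCs from the gate with a note; all-zero-variance expression matrices
are an error and single constant features are flagged `NA`, never a
silent NaN; confounded designs error with the aliased terms named. All
stochastic steps draw from seeds derived from a single configuration
seed, restore the caller's RNG state, and identical seeds reproduce
every file byte for byte.

## Problem sizes used by the tests

The test suite exercises the full default conditions (1 Mb, 200 genes,
24 libraries) once and reuses the cached run across checks; unit tests
run on a 30-gene, 200-kb miniature with the same structure. Oracle
comparisons use 100 random clustering instances, 1,000 random
transcripts, 100 random PWM/sequence pairs, a 500-feature null
calibration and 20 seeded enrichment replicates — sizes chosen so each
property is tested at meaningful scale while the whole suite stays
fast.
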