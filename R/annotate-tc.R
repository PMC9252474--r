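# Hierarchical genomic annotation of tag clusters, host-gene assignment,
# the 10%-contribution gate for intragenic TCs, primary/alternative and
# major/minor labels, and TC-usage diversity metrics.

tc_peak_ranges <- function(tcset) {
  GRanges(seqnames(tcset$gr), IRanges(tcset$gr$peak, width = 1L),
          strand = strand(tcset$gr))
}

# category region sets from the annotation (same-strand unless noted)
annotation_regions <- function(ann, promoter_halfwidth = 100L) {
  tx_tss <- GRanges(
    vapply(seq_along(ann$exons_by_tx), function(i)
      as.character(seqnames(ann$exons_by_tx[[i]])[1]), character(1)),
    IRanges(vapply(ann$exons_by_tx, tx_five_prime, numeric(1)), width = 1L),
    strand = vapply(seq_along(ann$exons_by_tx), function(i)
      as.character(strand(ann$exons_by_tx[[i]])[1]), character(1)))
  promoter <- suppressWarnings(trim(resize(tx_tss,
                                           2L * promoter_halfwidth + 1L,
                                           fix = "center")))
  promoter <- GRanges(seqnames(promoter),
                      IRanges(pmax(start(promoter), 1L), end(promoter)),
                      strand = strand(promoter))
  five_utr <- unlist(GRangesList(lapply(ann$transcripts$transcript_id,
                                        function(tx) leader_intervals(ann, tx))))
  cds <- if (length(ann$cds_by_tx)) unlist(ann$cds_by_tx, use.names = FALSE)
         else GRanges()
  introns <- unlist(GRangesList(lapply(ann$transcripts$transcript_id,
    function(tx) intron_intervals(ann$exons_by_tx[[tx]]))))
  # 3'UTR: exonic space downstream of the CDS 3' end
  three_utr <- unlist(GRangesList(lapply(ann$transcripts$transcript_id,
    function(tx) {
      ex <- ann$exons_by_tx[[tx]]
      cdss <- ann$cds_by_tx[[tx]]
      if (is.null(cdss) || !length(cdss)) return(GRanges())
      total <- sum(width(ex))
      cend <- genome_to_tx(ex, if (as.character(strand(ex)[1]) == "-")
        min(start(cdss)) else max(end(cdss)))
      if (cend >= total) return(GRanges())
      tx_range_to_genome(ex, cend + 1L, total)
    })))
  list(promoter = promoter, fiveUTR = five_utr, CDS = cds,
       intron = introns, threeUTR = three_utr, gene_body = ann$genes)
}

#' Hierarchically annotate tag clusters
#'
#' Each TC is assigned exactly one category from its peak position, by
#' precedence: promoter > fiveUTR > CDS > intron > threeUTR > antisense >
#' intergenic. "Promoter" means the peak falls within
#' `promoter_halfwidth` bp of any annotated transcript 5' end on the same
#' strand; "antisense" means the peak lies within a gene on the opposite
#' strand with no same-strand feature claiming it.
#'
#' @param tcset a `TagClusterSet` with called peaks.
#' @param ann a [GenomeAnnotation].
#' @param promoter_halfwidth promoter window half-width in bp (default 100).
#' @return Character vector of categories, one per TC.
#' @export
annotate_tcs <- function(tcset, ann, promoter_halfwidth = 100L) {
  peaks <- tc_peak_ranges(tcset)
  reg <- annotation_regions(ann, promoter_halfwidth)
  category <- rep("intergenic", length(peaks))
  sense_levels <- c("promoter", "fiveUTR", "CDS", "intron", "threeUTR")
  unset <- rep(TRUE, length(peaks))
  for (lv in sense_levels) {
    r <- reg[[lv]]
    if (!length(r)) next
    hit <- overlapsAny(peaks, r, ignore.strand = FALSE)
    category[unset & hit] <- lv
    unset <- unset & !hit
  }
  anti <- overlapsAny(peaks, invertStrand(reg$gene_body),
                      ignore.strand = FALSE)
  category[unset & anti] <- "antisense"
  factor(category, levels = c(sense_levels, "antisense", "intergenic"))
}

#' Assign TCs to host genes and apply the fractional-contribution gate
#'
#' Intragenic TCs (peak within the gene span or its promoter window, same
#' strand) are assigned to their host gene. The per-library contribution of
#' a TC is its TPM divided by the summed TPM of all of its gene's TCs; a TC
#' is retained for alternative-TSS analyses iff its contribution is at
#' least `min_contribution` in at least `min_libs` libraries.
#'
#' @param tcset a `TagClusterSet`.
#' @param ann a [GenomeAnnotation].
#' @param min_contribution fractional gate (default 0.10).
#' @param min_libs supporting libraries required (default 3).
#' @param promoter_halfwidth promoter window half-width (default 100).
#' @return data.frame with one row per TC: `tc_id`, `category`, `gene_id`
#'   (NA when not intragenic), `kept` (passed the gate), `contribution`
#'   (pooled mean TPM share), plus `peak`, `chrom`, `strand`.
#' @export
assign_and_filter_intragenic <- function(tcset, ann, min_contribution = 0.10,
                                         min_libs = 3L,
                                         promoter_halfwidth = 100L) {
  category <- annotate_tcs(tcset, ann, promoter_halfwidth)
  peaks <- tc_peak_ranges(tcset)
  # host gene: same-strand gene span extended upstream/downstream by the
  # promoter window so promoter TCs map to their gene
  ext <- suppressWarnings(ann$genes + promoter_halfwidth)
  ext <- GRanges(seqnames(ext), IRanges(pmax(start(ext), 1L), end(ext)),
                 strand = strand(ext), gene_id = ext$gene_id)
  hits <- findOverlaps(peaks, ext, ignore.strand = FALSE)
  gene_id <- rep(NA_character_, length(peaks))
  # nearest-TSS tie-break when a peak falls in two overlapping gene spans
  if (length(hits)) {
    qh <- queryHits(hits)
    cand <- data.frame(q = qh, g = ext$gene_id[subjectHits(hits)],
                       dist = abs(start(peaks)[qh] -
                                  ann$genes$most_upstream_tss[
                                    match(ext$gene_id[subjectHits(hits)],
                                          ann$genes$gene_id)]))
    cand <- cand[order(cand$q, cand$dist, cand$g), ]
    cand <- cand[!duplicated(cand$q), ]
    gene_id[cand$q] <- cand$g
  }
  gene_id[category == "antisense" | category == "intergenic"] <- NA_character_

  contribution <- rep(NA_real_, length(peaks))
  kept <- rep(FALSE, length(peaks))
  for (g in unique(gene_id[!is.na(gene_id)])) {
    idx <- which(!is.na(gene_id) & gene_id == g)
    sub <- tcset$tpm[idx, , drop = FALSE]
    tot <- colSums(sub)
    frac <- sweep(sub, 2, ifelse(tot == 0, Inf, tot), "/")
    kept[idx] <- rowSums(frac >= min_contribution) >= min_libs
    pooled <- rowMeans(tcset$tpm[idx, , drop = FALSE])
    psum <- sum(pooled)
    contribution[idx] <- if (psum > 0) pooled / psum else 0
  }
  data.frame(tc_id = tcset$gr$tc_id,
             chrom = as.character(seqnames(tcset$gr)),
             peak = tcset$gr$peak,
             strand = as.character(strand(tcset$gr)),
             category = as.character(category),
             gene_id = gene_id, contribution = contribution, kept = kept,
             stringsAsFactors = FALSE)
}

#' Label primary/alternative and major/minor TCs per gene
#'
#' A TC is "primary" when its peak lies within `promoter_halfwidth` bp of
#' the gene's most upstream annotated 5' end, otherwise "alternative". The
#' gene's highest-expressed retained TC (maximal mean TPM; 5'-most on ties)
#' is "major", the others "minor".
#'
#' @param assign data.frame from [assign_and_filter_intragenic].
#' @param tcset the matching `TagClusterSet`.
#' @param ann a [GenomeAnnotation].
#' @param promoter_halfwidth window half-width in bp (default 100).
#' @return `assign` with logical columns `is_primary`, `is_major` (NA for
#'   TCs that are not retained intragenic TCs).
#' @export
label_primary_major <- function(assign, tcset, ann,
                                promoter_halfwidth = 100L) {
  assign$is_primary <- NA
  assign$is_major <- NA
  mean_tpm <- rowMeans(tcset$tpm)[match(assign$tc_id, tcset$gr$tc_id)]
  for (g in unique(assign$gene_id[!is.na(assign$gene_id) & assign$kept])) {
    idx <- which(!is.na(assign$gene_id) & assign$gene_id == g & assign$kept)
    mup <- ann$genes$most_upstream_tss[match(g, ann$genes$gene_id)]
    assign$is_primary[idx] <- abs(assign$peak[idx] - mup) <= promoter_halfwidth
    val <- mean_tpm[idx]
    best <- which(val == max(val))
    if (length(best) > 1L) {
      minus <- assign$strand[idx[1]] == "-"
      pk <- assign$peak[idx[best]]
      best <- best[if (minus) which.max(pk) else which.min(pk)]
    }
    assign$is_major[idx] <- FALSE
    assign$is_major[idx[best]] <- TRUE
  }
  assign
}

#' Per-gene TC usage metrics: ranks, fractional usage, Simpson diversity
#'
#' Ranks retained TCs by decreasing pooled contribution (rank 1 = dominant
#' TC) and computes the Simpson diversity of TC usage, D = 1 - sum(p_i^2),
#' via `vegan::diversity`.
#'
#' @param assign labeled data.frame from [label_primary_major] (or
#'   [assign_and_filter_intragenic]).
#' @return list with `tc` (per-TC data.frame adding `rank` and
#'   `fractional_usage`) and `gene` (per-gene data.frame with `gene_id`,
#'   `n_tc`, `simpson`, `total_contribution_check`).
#' @export
usage_metrics <- function(assign) {
  assign$rank <- NA_integer_
  assign$fractional_usage <- NA_real_
  genes <- unique(assign$gene_id[!is.na(assign$gene_id) & assign$kept])
  res <- data.frame(gene_id = genes, n_tc = NA_integer_,
                    simpson = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    idx <- which(!is.na(assign$gene_id) & assign$gene_id == genes[k] &
                   assign$kept)
    p <- assign$contribution[idx]
    p <- p / sum(p)  # renormalize over retained TCs
    o <- order(-p)
    assign$rank[idx[o]] <- seq_along(idx)
    assign$fractional_usage[idx] <- p
    res$n_tc[k] <- length(idx)
    res$simpson[k] <- vegan::diversity(p, index = "simpson")
  }
  list(tc = assign, gene = res)
}
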