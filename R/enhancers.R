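# Bidirectionally transcribed (eRNA-like) locus detection with the
# Bhattacharyya balance score, plus the candidate filters and candidate
# differential expression.

#' Bhattacharyya balance of divergent transcription
#'
#' With observed strand proportions `p = (U, D) / (U + D)` and the ideal
#' balanced split `q = (1/2, 1/2)`, the Bhattacharyya coefficient is
#' `BC = sqrt(p1/2) + sqrt(p2/2)`. BC is 1 iff `U == D` and `sqrt(1/2)`
#' (~0.707) for fully one-sided signal.
#'
#' @param upstream_minus,downstream_plus non-negative tag counts
#'   (vectorized; a pair with both zero yields `NA`).
#' @return Numeric vector of balance coefficients in `[0, 1]`.
#' @export
balance_score <- function(upstream_minus, downstream_plus) {
  tot <- upstream_minus + downstream_plus
  bc <- sqrt(upstream_minus / tot * 0.5) + sqrt(downstream_plus / tot * 0.5)
  bc[tot == 0] <- NA_real_
  bc
}

pooled_strand_cumsum <- function(ctss, chrom, len) {
  pooled <- rowSums(ctss$counts)
  on_chrom <- as.character(seqnames(ctss$gr)) == chrom
  vplus <- numeric(len); vminus <- numeric(len)
  i <- on_chrom & as.character(strand(ctss$gr)) == "+"
  vplus[start(ctss$gr)[i]] <- pooled[i]
  i <- on_chrom & as.character(strand(ctss$gr)) == "-"
  vminus[start(ctss$gr)[i]] <- pooled[i]
  list(plus = cumsum(vplus), minus = cumsum(vminus))
}

#' Scan pooled CAGE signal for bidirectional enhancer candidates
#'
#' For each candidate midpoint `mid`, `U` is the pooled minus-strand signal
#' in `[mid - window/2, mid - 1]` and `D` the plus-strand signal in
#' `[mid, mid + window/2 - 1]`. Midpoints with both strands nonzero and
#' `balance_score(U, D) >= balance_min` pass; runs of passing midpoints are
#' collapsed to the midpoint with maximal `U + D` (leftmost on ties), and
#' candidates with overlapping windows are merged the same way.
#'
#' @param ctss a [CTSSMatrix] (signal pooled over libraries internally).
#' @param window total window size in bp (default 500; must be >= 2).
#' @param balance_min minimal Bhattacharyya coefficient (default 0.95).
#' @param seqlen optional named chromosome lengths.
#' @return `GRanges` of candidate windows with metadata `midpoint`,
#'   `balance`, `total` (pooled U + D).
#' @export
scan_bidirectional <- function(ctss, window = 500L, balance_min = 0.95,
                               seqlen = NULL) {
  if (window < 2L) stop("window must be >= 2 bp")
  hw <- as.integer(window %/% 2L)
  chroms <- unique(as.character(seqnames(ctss$gr)))
  out <- list()
  for (chrom in chroms) {
    len <- if (!is.null(seqlen) && chrom %in% names(seqlen))
      seqlen[[chrom]]
    else max(start(ctss$gr)[as.character(seqnames(ctss$gr)) == chrom]) + hw
    cums <- pooled_strand_cumsum(ctss, chrom, len)
    mids <- seq_len(len)
    lo_m <- pmax(mids - hw, 1L) - 1L  # cumsum index before window start
    hi_m <- pmax(mids - 1L, 0L)
    U <- ifelse(hi_m >= 1L, cums$minus[pmax(hi_m, 1L)], 0) -
      ifelse(lo_m >= 1L, cums$minus[pmax(lo_m, 1L)], 0)
    hi_p <- pmin(mids + hw - 1L, len)
    lo_p <- mids - 1L
    D <- cums$plus[hi_p] - ifelse(lo_p >= 1L, cums$plus[pmax(lo_p, 1L)], 0)
    bc <- balance_score(U, D)
    pass <- !is.na(bc) & U > 0 & D > 0 & bc >= balance_min
    if (!any(pass)) next
    total <- U + D
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    reps <- which(r$values)
    cand_mid <- vapply(reps, function(k) {
      span <- starts[k]:ends[k]
      span[which.max(total[span])]   # which.max returns first (leftmost)
    }, integer(1))
    gr <- GRanges(chrom, IRanges(pmax(cand_mid - hw, 1L),
                                 pmin(cand_mid + hw - 1L, len)),
                  strand = "*", midpoint = cand_mid,
                  balance = bc[cand_mid], total = total[cand_mid])
    # merge candidates with overlapping windows: keep max-total (leftmost)
    red <- reduce(gr, ignore.strand = TRUE)
    grp <- subjectHits(findOverlaps(gr, red, ignore.strand = TRUE))
    keep <- unlist(lapply(split(seq_along(gr), grp), function(idx)
      idx[which.max(gr$total[idx])]))
    out[[chrom]] <- gr[sort(keep)]
  }
  if (!length(out)) return(GRanges())
  sort(do.call(c, unname(out)), ignore.strand = TRUE)
}

# per-library upstream-minus / downstream-plus counts for candidates
candidate_library_counts <- function(cands, ctss) {
  up <- GRanges(seqnames(cands),
                IRanges(start(cands), pmax(cands$midpoint - 1L, start(cands))),
                strand = "-")
  dn <- GRanges(seqnames(cands), IRanges(cands$midpoint, end(cands)),
                strand = "+")
  count_in <- function(regions) {
    m <- matrix(0, length(regions), ncol(ctss$counts),
                dimnames = list(NULL, colnames(ctss$counts)))
    hits <- findOverlaps(ctss$gr, regions, ignore.strand = FALSE)
    if (length(hits)) {
      agg <- rowsum(ctss$counts[queryHits(hits), , drop = FALSE],
                    subjectHits(hits))
      m[as.integer(rownames(agg)), ] <- agg
    }
    m
  }
  list(U = count_in(up), D = count_in(dn))
}

#' Filter enhancer candidates
#'
#' Keeps candidates (1) with bidirectional signal (both `U > 0` and
#' `D > 0` in the same library) in at least `min_samples` libraries,
#' (2) whose midpoint lies in intergenic or intronic space, and (3) on a
#' nuclear chromosome. The genomic context of the midpoint is recorded.
#'
#' @param cands `GRanges` from [scan_bidirectional].
#' @param ann a [GenomeAnnotation].
#' @param ctss the [CTSSMatrix] with per-library signal.
#' @param min_samples minimal bidirectional libraries (default 3).
#' @return Filtered `GRanges` with added `support` and `context` columns.
#' @export
filter_candidates <- function(cands, ann, ctss, min_samples = 3L) {
  if (!length(cands)) return(cands)
  lc <- candidate_library_counts(cands, ctss)
  support <- rowSums(lc$U > 0 & lc$D > 0)
  mids <- GRanges(seqnames(cands), IRanges(cands$midpoint, width = 1L))
  in_gene <- overlapsAny(mids, ann$genes, ignore.strand = TRUE)
  all_exons <- unlist(ann$exons_by_tx, use.names = FALSE)
  in_exon <- overlapsAny(mids, all_exons, ignore.strand = TRUE)
  context <- ifelse(!in_gene, "intergenic",
                    ifelse(!in_exon, "intronic", "other"))
  nuclear <- as.character(seqnames(cands)) %in% ann$nuclear_chroms
  cands$support <- support
  cands$context <- context
  keep <- support >= min_samples & context %in% c("intergenic", "intronic") &
    nuclear
  cands[keep]
}

#' Differential expression of enhancer candidates
#'
#' Candidate expression per library is `U + D` (minus-strand upstream plus
#' plus-strand downstream tags within the candidate window), normalized to
#' tags per million, then fitted with the same moderated model and
#' contrasts as [fit_de].
#'
#' @param cands filtered candidates from [filter_candidates].
#' @param ctss the [CTSSMatrix].
#' @param ... passed to [fit_de].
#' @return list with `fit` (a `DEFit`) and `expression` (candidate x
#'   library TPM matrix).
#' @export
de_enhancers <- function(cands, ctss, ...) {
  if (!length(cands)) stop("no enhancer candidates to test")
  lc <- candidate_library_counts(cands, ctss)
  counts <- lc$U + lc$D
  rownames(counts) <- sprintf("ENH_%s_%d", seqnames(cands), cands$midpoint)
  denom <- ifelse(ctss$lib_sizes == 0, Inf, ctss$lib_sizes)
  tpm <- sweep(counts, 2, denom, "/") * 1e6
  fit <- fit_de(tpm, ctss$design, ...)
  list(fit = fit, expression = tpm)
}
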