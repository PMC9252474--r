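# CTSS support filtering, neighbor-clustering into tag clusters (TCs),
# quantification, TPM normalization, peak calling and expression filtering.

#' Filter CTSSs on library support
#'
#' Retains positions supported by at least `min_count` tags in at least
#' `min_libs` libraries. Library sizes are kept from the unfiltered matrix
#' so TPM normalization continues to use total mapped tags.
#'
#' @param ctss a [CTSSMatrix].
#' @param min_count minimal count per supporting library (default 1).
#' @param min_libs minimal number of supporting libraries (default 3, the
#'   smallest group size in a triplicated design).
#' @return Filtered [CTSSMatrix].
#' @export
filter_ctss <- function(ctss, min_count = 1L, min_libs = 3L) {
  stopifnot(min_count >= 1L, min_libs >= 1L)
  if (min_libs > ncol(ctss$counts))
    stop("min_libs (", min_libs, ") exceeds number of libraries (",
         ncol(ctss$counts), ")")
  keep <- rowSums(ctss$counts >= min_count) >= min_libs
  CTSSMatrix(ctss$gr[keep], ctss$counts[keep, , drop = FALSE],
             ctss$design, lib_sizes = ctss$lib_sizes)
}

#' Neighbor-cluster CTSSs into tag clusters
#'
#' Chains same-strand CTSSs whose consecutive genomic distance is at most
#' `max_dist` bp into one tag cluster (single-linkage along the chromosome;
#' strands never merge). The cluster interval spans the first to last member
#' position.
#'
#' @param ctss a filtered [CTSSMatrix].
#' @param max_dist maximal distance between consecutive member CTSSs
#'   (default 20 bp).
#' @return `GRanges` of tag clusters (sorted), with a `tc_id` column.
#' @export
cluster_ctss <- function(ctss, max_dist = 20L) {
  stopifnot(max_dist >= 0L)
  if (!length(ctss$gr)) return(GRanges())
  # positions p, q on the same strand chain iff |p - q| <= max_dist,
  # i.e. the gap between width-1 ranges is <= max_dist - 1
  tc <- reduce(ctss$gr, min.gapwidth = max_dist, ignore.strand = FALSE)
  tc <- sort(tc, ignore.strand = TRUE)
  tc$tc_id <- sprintf("TC_%s_%d_%d_%s", seqnames(tc), start(tc), end(tc),
                      ifelse(as.character(strand(tc)) == "+", "p", "m"))
  tc
}

#' Quantify tag clusters and normalize to TPM
#'
#' Per-library TC counts are the sums of member CTSS counts; TPM divides by
#' total library tags (not only clustered tags) times 1e6. Also calls the TC
#' peak: the member position with maximal pooled (summed over libraries)
#' count, ties broken by the 5'-most position in the direction of
#' transcription.
#'
#' @param tcs `GRanges` from [cluster_ctss].
#' @param ctss the [CTSSMatrix] the clusters were built from.
#' @return An object of class `TagClusterSet`: list with `gr` (TC ranges
#'   with `peak` and `tc_id`), `counts`, `tpm`, `lib_sizes`, `design`.
#' @export
quantify_tcs <- function(tcs, ctss) {
  hits <- findOverlaps(ctss$gr, tcs, ignore.strand = FALSE)
  n_tc <- length(tcs)
  counts <- matrix(0, n_tc, ncol(ctss$counts),
                   dimnames = list(tcs$tc_id, colnames(ctss$counts)))
  agg <- rowsum(ctss$counts[queryHits(hits), , drop = FALSE],
                subjectHits(hits))
  counts[as.integer(rownames(agg)), ] <- agg

  # peak: argmax of pooled signal, 5'-most on ties
  pooled <- rowSums(ctss$counts)
  peak <- rep(NA_integer_, n_tc)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  minus <- as.character(strand(tcs)) == "-"
  for (i in unique(sh)) {
    mem <- qh[sh == i]
    pos <- start(ctss$gr)[mem]
    val <- pooled[mem]
    best <- val == max(val)
    peak[i] <- if (minus[i]) max(pos[best]) else min(pos[best])
  }
  if (anyNA(peak)) stop("tag cluster without member CTSS")
  tcs$peak <- peak

  if (any(ctss$lib_sizes == 0))
    warning("library with zero total tags; its TPM set to 0")
  denom <- ifelse(ctss$lib_sizes == 0, Inf, ctss$lib_sizes)
  tpm <- sweep(counts, 2, denom, "/") * 1e6
  structure(list(gr = tcs, counts = counts, tpm = tpm,
                 lib_sizes = ctss$lib_sizes, design = ctss$design),
            class = "TagClusterSet")
}

#' @export
print.TagClusterSet <- function(x, ...) {
  cat("TagClusterSet:", length(x$gr), "tag clusters x",
      ncol(x$counts), "libraries\n")
  invisible(x)
}

#' Filter tag clusters on TPM support
#'
#' Retains TCs with at least `min_tpm` in at least `min_libs` libraries.
#'
#' @param tcset a `TagClusterSet` from [quantify_tcs].
#' @param min_tpm minimal TPM (default 1).
#' @param min_libs minimal number of supporting libraries (default 3).
#' @return Filtered `TagClusterSet`.
#' @export
filter_tcs <- function(tcset, min_tpm = 1, min_libs = 3L) {
  stopifnot(min_tpm >= 0, min_libs >= 1L)
  if (min_libs > ncol(tcset$tpm))
    stop("min_libs exceeds number of libraries")
  keep <- rowSums(tcset$tpm >= min_tpm) >= min_libs
  structure(list(gr = tcset$gr[keep],
                 counts = tcset$counts[keep, , drop = FALSE],
                 tpm = tcset$tpm[keep, , drop = FALSE],
                 lib_sizes = tcset$lib_sizes, design = tcset$design),
            class = "TagClusterSet")
}
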