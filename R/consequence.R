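# Biological consequences of alternative TSSs: protein-domain disruption,
# target-peptide exclusion and uORF skipping. Boundaries are strict and
# half-open in spirit: a TC peak exactly at a feature's 5' genomic edge
# counts as "within".

# TRUE when `pos` is at or downstream (transcription direction) of
# `boundary` on the given strand
at_or_downstream <- function(pos, boundary, strand) {
  ifelse(strand == "-", pos <= boundary, pos >= boundary)
}

#' Map protein-domain amino-acid coordinates to genomic intervals
#'
#' A domain spanning amino acids `[aa_start, aa_end]` covers CDS
#' nucleotides `[3*(aa_start-1)+1, 3*aa_end]`; these are walked through the
#' transcript's CDS exon structure into one genomic segment per exon piece.
#' Segment widths always sum to `3 * (aa_end - aa_start + 1)`.
#'
#' @param ann a [GenomeAnnotation] whose `domains` table (or the `domains`
#'   argument) holds `transcript_id`, `aa_start`, `aa_end`, `label`.
#' @param domains optional data.frame overriding `ann$domains`.
#' @return `GRangesList`, one element per domain row, named
#'   `<transcript_id>:<label>`.
#' @export
domains_to_genome <- function(ann, domains = NULL) {
  if (is.null(domains)) domains <- ann$domains
  stopifnot(!is.null(domains))
  out <- vector("list", nrow(domains))
  for (i in seq_len(nrow(domains))) {
    tx <- domains$transcript_id[i]
    cds <- ann$cds_by_tx[[tx]]
    if (is.null(cds) || !length(cds))
      stop("transcript without CDS: ", tx)
    aa_len <- sum(width(cds)) %/% 3L
    if (domains$aa_end[i] > aa_len)
      stop("domain beyond protein length for transcript ", tx)
    nt_start <- 3L * (domains$aa_start[i] - 1L) + 1L
    nt_end <- 3L * domains$aa_end[i]
    out[[i]] <- tx_range_to_genome(cds, nt_start, nt_end)
  }
  names(out) <- paste0(domains$transcript_id, ":", domains$label)
  GRangesList(out)
}

#' Classify TCs as protein-domain disruptive
#'
#' A sense intragenic TC is domain disruptive when its peak lies within a
#' domain's genomic segments or downstream (in transcription direction) of
#' the 5'-most genomic start of any domain of the same gene: transcripts
#' initiated there cannot encode the complete domain.
#'
#' @param assign per-TC data.frame from [assign_and_filter_intragenic].
#' @param ann a [GenomeAnnotation] with a `domains` table.
#' @return Logical vector per TC (`NA` for TCs without an assigned gene or
#'   whose gene has no domain record).
#' @export
classify_domain_disruption <- function(assign, ann) {
  if (is.null(ann$domains)) return(rep(NA, nrow(assign)))
  dom_gene <- ann$transcripts$gene_id[match(ann$domains$transcript_id,
                                            ann$transcripts$transcript_id)]
  segs <- domains_to_genome(ann)
  # 5'-most genomic segment start per domain, in transcription direction
  dom5 <- vapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    if (as.character(strand(s)[1]) == "-") max(end(s)) else min(start(s))
  }, numeric(1))
  res <- rep(NA, nrow(assign))
  for (i in seq_len(nrow(assign))) {
    g <- assign$gene_id[i]
    if (is.na(g) || assign$category[i] %in% c("antisense", "intergenic"))
      next
    j <- which(dom_gene == g)
    if (!length(j)) next
    res[i] <- any(at_or_downstream(assign$peak[i], dom5[j],
                                   assign$strand[i]))
  }
  res
}

#' Classify TCs as target-peptide excluding
#'
#' The peptide-coding region is approximated as the first
#' `3 * cleavage_aa` coding nucleotides, mapped to the genome. A TC
#' excludes the target peptide when its peak lies within or downstream of
#' that genomic span, so the encoded protein lacks its localization signal.
#'
#' @param assign per-TC data.frame from [assign_and_filter_intragenic].
#' @param ann a [GenomeAnnotation] with a `target_peptides` table.
#' @return Logical vector per TC (`NA` when the gene has no target-peptide
#'   record).
#' @export
classify_target_peptide <- function(assign, ann) {
  tp <- ann$target_peptides
  if (is.null(tp)) return(rep(NA, nrow(assign)))
  tp_gene <- ann$transcripts$gene_id[match(tp$transcript_id,
                                           ann$transcripts$transcript_id)]
  pep5 <- vapply(seq_len(nrow(tp)), function(i) {
    cds <- ann$cds_by_tx[[tp$transcript_id[i]]]
    segs <- tx_range_to_genome(cds, 1L, 3L * tp$cleavage_aa[i])
    if (as.character(strand(segs)[1]) == "-") max(end(segs))
    else min(start(segs))
  }, numeric(1))
  res <- rep(NA, nrow(assign))
  for (i in seq_len(nrow(assign))) {
    g <- assign$gene_id[i]
    if (is.na(g) || assign$category[i] %in% c("antisense", "intergenic"))
      next
    j <- which(tp_gene == g)
    if (!length(j)) next
    res[i] <- any(at_or_downstream(assign$peak[i], pep5[j],
                                   assign$strand[i]))
  }
  res
}

#' Scan an mRNA leader for upstream open reading frames
#'
#' Finds every ATG...in-frame-stop ORF that lies fully within the leader
#' (the sequence 5' of the main start codon), of length at least
#' `min_len_nt` (stop codon included). Overlapping uORFs are all reported.
#'
#' @param leader_seq character or `DNAString`: the leader sequence in
#'   transcript orientation (5'->3').
#' @param min_len_nt minimal uORF length in nt, stop included (default 6).
#' @return data.frame `tx_start`, `tx_end` (1-based closed, within the
#'   leader), `length_nt`; zero rows when none found.
#' @export
scan_uorfs <- function(leader_seq, min_len_nt = 6L) {
  s <- toupper(as.character(leader_seq))
  n <- nchar(s)
  empty <- data.frame(tx_start = integer(0), tx_end = integer(0),
                      length_nt = integer(0))
  if (n < min_len_nt) return(empty)
  stops <- c("TAA", "TAG", "TGA")
  starts <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(empty)
  rows <- list()
  for (st in starts) {
    pos <- st + 3L
    while (pos + 2L <= n) {
      codon <- substr(s, pos, pos + 2L)
      if (codon %in% stops) {
        len <- pos + 2L - st + 1L
        if (len >= min_len_nt)
          rows[[length(rows) + 1L]] <-
            data.frame(tx_start = st, tx_end = pos + 2L, length_nt = len)
        break
      }
      pos <- pos + 3L
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$tx_start, out$tx_end), , drop = FALSE]
}

#' Classify uORF content of TC-defined transcripts
#'
#' A TC "skips" a uORF when its peak lies within or downstream of the
#' uORF's genomic interval (the transcript starting there cannot contain
#' the complete uORF); a peak strictly upstream of the uORF start retains
#' it.
#'
#' @param assign per-TC data.frame from [assign_and_filter_intragenic].
#' @param ann a [GenomeAnnotation] with a `uorfs` table (transcript
#'   coordinates within the leader-containing transcript).
#' @return list with `per_uorf` (long data.frame: tc_id, gene_id,
#'   transcript_id, uorf index, skipped) and `skips_any` (logical per TC,
#'   `NA` when the gene has no uORF).
#' @export
classify_uorf_content <- function(assign, ann) {
  uo <- ann$uorfs
  if (is.null(uo))
    return(list(per_uorf = data.frame(), skips_any = rep(NA, nrow(assign))))
  uo_gene <- ann$transcripts$gene_id[match(uo$transcript_id,
                                           ann$transcripts$transcript_id)]
  # 5'-most genomic position of each uORF in transcription direction
  uo5 <- vapply(seq_len(nrow(uo)), function(i) {
    ex <- ann$exons_by_tx[[uo$transcript_id[i]]]
    tx_to_genome(ex, uo$tx_start[i])
  }, numeric(1))
  strands <- vapply(seq_len(nrow(uo)), function(i)
    as.character(strand(ann$exons_by_tx[[uo$transcript_id[i]]])[1]),
    character(1))
  rows <- list()
  skips_any <- rep(NA, nrow(assign))
  for (i in seq_len(nrow(assign))) {
    g <- assign$gene_id[i]
    if (is.na(g) || assign$category[i] %in% c("antisense", "intergenic"))
      next
    j <- which(uo_gene == g)
    if (!length(j)) next
    sk <- at_or_downstream(assign$peak[i], uo5[j], strands[j])
    skips_any[i] <- any(sk)
    rows[[length(rows) + 1L]] <-
      data.frame(tc_id = assign$tc_id[i], gene_id = g,
                 transcript_id = uo$transcript_id[j], uorf = j,
                 skipped = sk, stringsAsFactors = FALSE)
  }
  list(per_uorf = if (length(rows)) do.call(rbind, rows) else data.frame(),
       skips_any = skips_any)
}

#' Summarise the consequence class of each TC
#'
#' One class per TC with precedence domain_disruptive >
#' target_peptide_excluding > uorf_skipping > none. Only alternative
#' (non-primary) TCs are interesting biologically, but all retained sense
#' TCs are classified; filter on `is_primary` downstream as needed.
#'
#' @param assign labeled data.frame from [label_primary_major].
#' @param ann a [GenomeAnnotation].
#' @return `assign` with logical columns `domain_disruptive`,
#'   `target_peptide_excluding`, `uorf_skipping` and a `consequence`
#'   character column.
#' @export
classify_consequences <- function(assign, ann) {
  assign$domain_disruptive <- classify_domain_disruption(assign, ann)
  assign$target_peptide_excluding <- classify_target_peptide(assign, ann)
  assign$uorf_skipping <- classify_uorf_content(assign, ann)$skips_any
  cls <- rep("none", nrow(assign))
  cls[assign$uorf_skipping %in% TRUE] <- "uorf_skipping"
  cls[assign$target_peptide_excluding %in% TRUE] <- "target_peptide_excluding"
  cls[assign$domain_disruptive %in% TRUE] <- "domain_disruptive"
  assign$consequence <- cls
  assign
}
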