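# Gene-model container and transcript <-> genome coordinate mapping.
#
# Internal convention: GRanges everywhere (1-based, closed). GFF3 I/O is
# already 1-based closed; BED I/O (see ctss.R) converts from 0-based
# half-open. Transcript coordinates are 1-based, measured 5'->3' along the
# spliced transcript.

#' Construct a GenomeAnnotation
#'
#' Bundles gene models (genes, transcripts, exons, CDS) with the optional
#' side tables used by consequence classification: protein domains, target
#' peptide cleavage sites and uORFs.
#'
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons_by_tx named `GRangesList`, one element per transcript.
#' @param cds_by_tx named `GRangesList`; transcripts without CDS may be
#'   absent or have empty elements.
#' @param domains data.frame (`transcript_id`, `aa_start`, `aa_end`,
#'   `label`) in 1-based amino-acid coordinates, or `NULL`.
#' @param target_peptides data.frame (`transcript_id`, `cleavage_aa`,
#'   `kind`), or `NULL`.
#' @param uorfs data.frame (`transcript_id`, `tx_start`, `tx_end`) in
#'   1-based closed transcript coordinates within the leader, or `NULL`.
#' @param seqlen named integer vector of chromosome lengths.
#' @param nuclear_chroms character vector of chromosomes considered
#'   nuclear; defaults to all chromosomes.
#'
#' @return An object of class `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(genes, transcripts, exons_by_tx,
                             cds_by_tx = NULL, domains = NULL,
                             target_peptides = NULL, uorfs = NULL,
                             seqlen = NULL, nuclear_chroms = NULL) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$gene_id))
  stopifnot(all(c("transcript_id", "gene_id") %in% names(transcripts)))
  genes <- sort(genes, ignore.strand = TRUE)
  transcripts <- transcripts[order(transcripts$gene_id,
                                   transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL
  if (nrow(transcripts))
    exons_by_tx <- sort_within_groups(exons_by_tx[transcripts$transcript_id])
  if (is.null(cds_by_tx)) cds_by_tx <- GRangesList()
  if (length(cds_by_tx)) cds_by_tx <- sort_within_groups(cds_by_tx)

  # most upstream annotated 5' end per gene (5'-most base over transcripts)
  tss <- vapply(seq_len(nrow(transcripts)), function(i) {
    ex <- exons_by_tx[[transcripts$transcript_id[i]]]
    tx_five_prime(ex)
  }, numeric(1))
  mup <- vapply(genes$gene_id, function(g) {
    v <- tss[transcripts$gene_id == g]
    if (!length(v)) return(NA_real_)
    if (as.character(strand(genes[match(g, genes$gene_id)])) == "-")
      max(v) else min(v)
  }, numeric(1))
  genes$most_upstream_tss <- as.integer(mup)

  if (is.null(seqlen)) {
    seqlen <- tapply(end(genes), as.character(seqnames(genes)), max)
    seqlen <- setNames(as.integer(seqlen), names(seqlen))
  }
  if (is.null(nuclear_chroms)) nuclear_chroms <- names(seqlen)

  structure(list(genes = genes, transcripts = transcripts,
                 exons_by_tx = exons_by_tx, cds_by_tx = cds_by_tx,
                 domains = domains, target_peptides = target_peptides,
                 uorfs = uorfs, seqlen = seqlen,
                 nuclear_chroms = nuclear_chroms),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", length(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(x$seqlen), "sequence(s)\n")
  if (!is.null(x$domains)) cat("  domains:", nrow(x$domains), "\n")
  if (!is.null(x$target_peptides))
    cat("  target peptides:", nrow(x$target_peptides), "\n")
  if (!is.null(x$uorfs)) cat("  uORFs:", nrow(x$uorfs), "\n")
  invisible(x)
}

# sort ranges by start position within each list element (one S4 pass)
sort_within_groups <- function(grl) {
  u <- unlist(grl, use.names = FALSE)
  f <- factor(rep(names(grl), lengths(grl)), levels = names(grl))
  o <- order(as.integer(f), start(u))
  split(u[o], f[o])
}

# genomic position of the spliced-transcript 5' end
tx_five_prime <- function(exons) {
  if (as.character(strand(exons)[1]) == "-") max(end(exons)) else min(start(exons))
}

# exons ordered 5'->3' in transcript orientation
sort_tx_exons <- function(exons) {
  exons <- sort(exons, ignore.strand = TRUE)
  if (as.character(strand(exons)[1]) == "-") rev(exons) else exons
}

#' Map transcript positions to genomic coordinates
#'
#' Positions are 1-based along the spliced transcript, counted from the
#' transcript 5' end; introns are skipped. `genome_to_tx()` is the exact
#' inverse on valid positions.
#'
#' @param exons `GRanges` of one transcript's exons (any order; single
#'   strand).
#' @param tx_pos integer vector of transcript positions.
#' @return Integer vector of genomic positions.
#' @export
tx_to_genome <- function(exons, tx_pos) {
  ex <- sort_tx_exons(exons)
  w <- width(ex)
  cs <- cumsum(w)
  if (any(tx_pos < 1L | tx_pos > cs[length(cs)]))
    stop("tx_pos out of range [1, ", cs[length(cs)], "]")
  idx <- findInterval(tx_pos - 1L, c(0L, cs))
  off <- tx_pos - c(0L, cs)[idx]          # 1-based offset within exon
  minus <- as.character(strand(ex)[1]) == "-"
  if (minus) as.integer(end(ex)[idx] - off + 1L)
  else       as.integer(start(ex)[idx] + off - 1L)
}

#' @rdname tx_to_genome
#' @param g_pos integer vector of genomic positions lying within exons.
#' @export
genome_to_tx <- function(exons, g_pos) {
  ex <- sort_tx_exons(exons)
  w <- width(ex)
  cs0 <- c(0L, cumsum(w)[-length(w)])
  res <- rep(NA_integer_, length(g_pos))
  minus <- as.character(strand(ex)[1]) == "-"
  for (i in seq_along(ex)) {
    hit <- g_pos >= start(ex)[i] & g_pos <= end(ex)[i]
    if (!any(hit)) next
    res[hit] <- if (minus) cs0[i] + (end(ex)[i] - g_pos[hit] + 1L)
                else       cs0[i] + (g_pos[hit] - start(ex)[i] + 1L)
  }
  if (anyNA(res)) stop("genomic position not within transcript exons")
  as.integer(res)
}

# Map a closed transcript interval [tx_start, tx_end] to genomic segments
# (one GRanges row per exon piece, genomic order).
tx_range_to_genome <- function(exons, tx_start, tx_end) {
  stopifnot(tx_start >= 1L, tx_end >= tx_start)
  ex <- sort_tx_exons(exons)
  w <- width(ex)
  cs <- cumsum(w)
  cs0 <- c(0L, cs[-length(cs)])
  if (tx_end > cs[length(cs)]) stop("transcript interval beyond spliced length")
  lo <- pmax(tx_start, cs0 + 1L)
  hi <- pmin(tx_end, cs)
  keep <- lo <= hi
  minus <- as.character(strand(ex)[1]) == "-"
  if (minus) {
    gs <- end(ex) - (hi - cs0) + 1L
    ge <- end(ex) - (lo - cs0) + 1L
  } else {
    gs <- start(ex) + (lo - cs0) - 1L
    ge <- start(ex) + (hi - cs0) - 1L
  }
  out <- GRanges(seqnames(ex)[keep],
                 IRanges(gs[keep], ge[keep]),
                 strand = strand(ex)[keep])
  sort(out, ignore.strand = TRUE)
}

# spliced transcript coordinates of the CDS start (1-based); NA if no CDS
cds_tx_start <- function(ann, transcript_id) {
  cds <- ann$cds_by_tx[[transcript_id]]
  if (is.null(cds) || !length(cds)) return(NA_integer_)
  genome_to_tx(ann$exons_by_tx[[transcript_id]], tx_five_prime(cds))
}

# leader (5'UTR) genomic intervals per transcript; empty if no CDS or
# CDS starts at position 1
leader_intervals <- function(ann, transcript_id) {
  cstart <- cds_tx_start(ann, transcript_id)
  if (is.na(cstart) || cstart <= 1L)
    return(GRanges())
  tx_range_to_genome(ann$exons_by_tx[[transcript_id]], 1L, cstart - 1L)
}

# intron intervals for one transcript (gaps between exons)
intron_intervals <- function(exons) {
  ex <- sort(exons, ignore.strand = TRUE)
  if (length(ex) < 2L) return(GRanges())
  GRanges(seqnames(ex)[-1],
          IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L),
          strand = strand(ex)[-1])
}

gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read a GFF3 gene annotation
#'
#' Expects gene/mRNA/exon/CDS rows linked by `ID`/`Parent` attributes
#' (1-based closed coordinates, the GFF3 convention). Transcripts whose
#' total CDS length is not divisible by 3 are kept with a warning.
#'
#' @param path path to a GFF3 file.
#' @param seqlen optional named chromosome lengths (read from
#'   `##sequence-region` pragmas when present).
#' @return A [GenomeAnnotation].
#' @export
read_gff3 <- function(path, seqlen = NULL) {
  lines <- readLines(path)
  preg <- grep("^##sequence-region", lines, value = TRUE)
  if (is.null(seqlen) && length(preg)) {
    parts <- strsplit(preg, "[[:space:]]+")
    seqlen <- setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
                       vapply(parts, function(p) p[2], character(1)))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop("no feature rows in ", path)
  f <- read.table(text = body, sep = "\t", quote = "", comment.char = "",
                  col.names = c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attr"),
                  colClasses = c("character", "character", "character",
                                 "integer", "integer", "character",
                                 "character", "character", "character"))
  id <- gff3_attr(f$attr, "ID")
  parent <- gff3_attr(f$attr, "Parent")

  gi <- f$type == "gene"
  genes <- GRanges(f$seqid[gi], IRanges(f$start[gi], f$end[gi]),
                   strand = f$strand[gi], gene_id = id[gi])
  ti <- f$type == "mRNA"
  bad <- ti & !(parent %in% id[gi])
  if (any(bad))
    stop("mRNA with unknown gene parent: ",
         paste(id[bad], collapse = ", "))
  transcripts <- data.frame(transcript_id = id[ti], gene_id = parent[ti],
                            stringsAsFactors = FALSE)
  ei <- f$type %in% c("exon", "CDS")
  bad <- ei & !(parent %in% transcripts$transcript_id)
  if (any(bad))
    stop("exon/CDS with unknown transcript parent: ",
         paste(unique(parent[bad]), collapse = ", "))
  make_grl <- function(type) {
    k <- f$type == type
    gr <- GRanges(f$seqid[k], IRanges(f$start[k], f$end[k]),
                  strand = f$strand[k])
    spl <- split(gr, factor(parent[k], levels = transcripts$transcript_id))
    spl[lengths(spl) > 0L]
  }
  exons_by_tx <- make_grl("exon")
  cds_by_tx <- make_grl("CDS")
  if (length(cds_by_tx)) {
    clen <- sum(width(cds_by_tx))
    off <- names(clen)[clen %% 3L != 0L]
    if (length(off))
      warning("CDS length not divisible by 3 for: ",
              paste(off, collapse = ", "), " (kept)")
  }
  missing_ex <- setdiff(transcripts$transcript_id, names(exons_by_tx))
  if (length(missing_ex))
    stop("transcript without exons: ", paste(missing_ex, collapse = ", "))
  GenomeAnnotation(genes, transcripts, exons_by_tx, cds_by_tx,
                   seqlen = seqlen)
}

#' Write a GenomeAnnotation as GFF3
#'
#' @param ann a [GenomeAnnotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (s in names(ann$seqlen))
    writeLines(sprintf("##sequence-region %s 1 %d", s, ann$seqlen[[s]]), con)
  rows <- character(0)
  fmt <- function(chrom, start, end, type, strand, attr)
    sprintf("%s\tcagetc\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attr)
  for (i in seq_along(ann$genes)) {
    g <- ann$genes[i]
    gid <- g$gene_id
    rows <- c(rows, fmt(as.character(seqnames(g)), start(g), end(g), "gene",
                        as.character(strand(g)), paste0("ID=", gid)))
    txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gid]
    for (tx in txs) {
      ex <- sort(ann$exons_by_tx[[tx]], ignore.strand = TRUE)
      rows <- c(rows, fmt(as.character(seqnames(ex)[1]), min(start(ex)),
                          max(end(ex)), "mRNA", as.character(strand(ex)[1]),
                          paste0("ID=", tx, ";Parent=", gid)))
      for (j in seq_along(ex))
        rows <- c(rows, fmt(as.character(seqnames(ex)[j]), start(ex)[j],
                            end(ex)[j], "exon", as.character(strand(ex)[j]),
                            paste0("Parent=", tx)))
      cds <- ann$cds_by_tx[[tx]]
      if (!is.null(cds) && length(cds)) {
        cds <- sort(cds, ignore.strand = TRUE)
        for (j in seq_along(cds))
          rows <- c(rows, fmt(as.character(seqnames(cds)[j]), start(cds)[j],
                              end(cds)[j], "CDS",
                              as.character(strand(cds)[j]),
                              paste0("Parent=", tx)))
      }
    }
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read consequence side tables
#'
#' Tab-separated tables keyed by `transcript_id`: protein domains
#' (`aa_start`, `aa_end`, `label`; 1-based amino acids), target peptides
#' (`cleavage_aa`, `kind`) and uORFs (`tx_start`, `tx_end`; 1-based closed
#' transcript coordinates).
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame.
#' @export
read_domain_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "aa_start", "aa_end", "label") %in% names(d)))
  stopifnot(all(d$aa_start >= 1L), all(d$aa_end >= d$aa_start))
  d
}

#' @rdname read_domain_table
#' @export
read_target_peptide_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "cleavage_aa", "kind") %in% names(d)))
  stopifnot(all(d$cleavage_aa >= 1L))
  d
}

#' @rdname read_domain_table
#' @export
read_uorf_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "tx_start", "tx_end") %in% names(d)))
  len <- d$tx_end - d$tx_start + 1L
  stopifnot(all(len >= 6L), all(len %% 3L == 0L))
  d
}
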