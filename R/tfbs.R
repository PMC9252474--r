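# JASPAR-format PWM handling, promoter definition anchored on CAGE TC
# peaks, log-odds scanning with a min-max-normalized relative score, and
# binding-site enrichment of gene clusters against the genome-wide
# promoter background.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Counts (or probabilities) are normalized per position with a pseudocount
#' split by the uniform background; log-odds are `log2(p / 0.25)`.
#'
#' @param matrix_id identifier.
#' @param counts 4 x width numeric matrix, rows A, C, G, T.
#' @param name optional matrix name.
#' @param pseudocount total pseudocount per position (default 0.8).
#' @return An object of class `PWM` with elements `matrix_id`, `name`,
#'   `counts`, `probs`, `logodds`, `score_range`.
#' @export
pwm <- function(matrix_id, counts, name = matrix_id, pseudocount = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L, all(counts >= 0))
  rownames(counts) <- BASES
  probs <- sweep(counts + pseudocount / 4,
                 2, colSums(counts) + pseudocount, "/")
  logodds <- log2(probs / 0.25)
  structure(list(matrix_id = matrix_id, name = name, counts = counts,
                 probs = probs, logodds = logodds,
                 score_range = c(min = sum(apply(logodds, 2, min)),
                                 max = sum(apply(logodds, 2, max)))),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$matrix_id, "(", x$name, "), width", ncol(x$counts), "\n")
  invisible(x)
}

#' Read PWMs from a JASPAR-format text file
#'
#' Parses the JASPAR 2016+ text format: a `>ID NAME` header followed by
#' four base rows like `A [ 3 5 ... ]` (brackets optional).
#'
#' @param path path to the JASPAR file.
#' @param pseudocount passed to [pwm].
#' @return Named list of `PWM` objects (empty with a warning for an empty
#'   file).
#' @export
read_jaspar <- function(path, pseudocount = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty JASPAR file: ", path)
    return(list())
  }
  heads <- grep("^>", lines)
  out <- list()
  for (k in seq_along(heads)) {
    h <- heads[k]
    stop_at <- if (k < length(heads)) heads[k + 1] - 1L else length(lines)
    hdr <- strsplit(sub("^>", "", lines[h]), "[[:space:]]+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    block <- lines[(h + 1L):stop_at]
    if (length(block) != 4L)
      stop("matrix ", id, ": expected 4 base rows, got ", length(block))
    rows <- lapply(block, function(l) {
      base <- sub("^([ACGT]).*", "\\1", l)
      nums <- gsub("[][ACGTacgt]", " ", l)
      list(base = base, vals = as.numeric(strsplit(trimws(nums),
                                                   "[[:space:]]+")[[1]]))
    })
    lens <- vapply(rows, function(r) length(r$vals), integer(1))
    if (length(unique(lens)) != 1L)
      stop("ragged base rows in matrix ", id)
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- vapply(rows, `[[`, character(1), "base")
    m <- m[BASES, , drop = FALSE]
    out[[id]] <- pwm(id, m, name = nm, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR text format
#'
#' @param pwms named list of `PWM` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$matrix_id, " ", p$name), con)
    for (b in BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

seq_to_index <- function(s) {
  x <- match(strsplit(toupper(as.character(s)), "")[[1]], BASES)
  x  # NA for N and other ambiguity codes
}

scan_one_strand <- function(idx, lo) {
  w <- ncol(lo)
  n <- length(idx)
  if (n < w) return(numeric(0))
  nwin <- n - w + 1L
  sc <- numeric(nwin)
  for (j in seq_len(w)) {
    v <- lo[, j][idx[j:(j + nwin - 1L)]]
    sc <- sc + v
  }
  sc  # NA where a window contains a non-ACGT base
}

#' Scan a sequence for PWM matches with a relative-score threshold
#'
#' Both strands are scanned with the matrix log-odds; each window's score
#' `S` is min-max normalized to `(S - S_min) / (S_max - S_min)` where
#' `S_min`/`S_max` are the matrix's attainable extremes, and windows
#' reaching `min_similarity` are reported. Windows containing a non-ACGT
#' base are skipped.
#'
#' @param sequence character or `DNAString` over A/C/G/T/N.
#' @param p a `PWM`.
#' @param min_similarity minimal relative score (default 0.70).
#' @return data.frame `start` (1-based on the given sequence, both
#'   strands), `strand`, `rel_score`; zero rows when the sequence is
#'   shorter than the matrix.
#' @export
pwm_scan <- function(sequence, p, min_similarity = 0.70) {
  stopifnot(is(p, "PWM"))
  s <- toupper(as.character(sequence))
  w <- ncol(p$logodds)
  empty <- data.frame(start = integer(0), strand = character(0),
                      rel_score = numeric(0))
  if (nchar(s) < w) return(empty)
  rng <- p$score_range
  norm <- function(sc) (sc - rng["min"]) / (rng["max"] - rng["min"])
  idx_f <- seq_to_index(s)
  sc_f <- norm(scan_one_strand(idx_f, p$logodds))
  rc <- as.character(reverseComplement(DNAString(s)))
  sc_r <- norm(scan_one_strand(seq_to_index(rc), p$logodds))
  n <- nchar(s)
  hits_f <- which(!is.na(sc_f) & sc_f >= min_similarity)
  hits_r <- which(!is.na(sc_r) & sc_r >= min_similarity)
  out <- rbind(
    if (length(hits_f))
      data.frame(start = hits_f, strand = "+",
                 rel_score = unname(sc_f[hits_f]))
    else empty,
    if (length(hits_r))
      data.frame(start = n - w + 2L - hits_r, strand = "-",
                 rel_score = unname(sc_r[hits_r]))
    else empty)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Define CAGE-anchored promoter regions
#'
#' For each gene the anchor is the TC peak closest to the gene's annotated
#' (most upstream) TSS; the promoter is the `width` bp immediately
#' upstream of the anchor in the direction of transcription, truncated at
#' chromosome edges (truncation flagged).
#'
#' @param ann a [GenomeAnnotation].
#' @param assign per-TC data.frame from [assign_and_filter_intragenic].
#' @param width promoter width in bp (default 500).
#' @return `GRanges` (strand = gene strand) with `gene_id`, `anchor`,
#'   `truncated`; genes without a TC are skipped.
#' @export
define_promoters <- function(ann, assign, width = 500L) {
  rows <- list()
  for (i in seq_along(ann$genes)) {
    g <- ann$genes[i]
    gid <- g$gene_id
    idx <- which(!is.na(assign$gene_id) & assign$gene_id == gid &
                   assign$kept)
    if (!length(idx)) next
    d <- abs(assign$peak[idx] - g$most_upstream_tss)
    anchor <- assign$peak[idx][which.min(d)]
    chrom <- as.character(seqnames(g))
    len <- ann$seqlen[[chrom]]
    if (as.character(strand(g)) == "-") {
      s <- anchor + 1L
      e <- min(anchor + width, len)
    } else {
      s <- max(anchor - width, 1L)
      e <- anchor - 1L
    }
    if (e < s) next
    rows[[length(rows) + 1L]] <-
      GRanges(chrom, IRanges(s, e), strand = strand(g), gene_id = gid,
              anchor = anchor, truncated = (e - s + 1L) < width)
  }
  if (!length(rows)) return(GRanges())
  sort(do.call(c, rows), ignore.strand = TRUE)
}

#' Count PWM matches per promoter
#'
#' Extracts each promoter sequence (reverse-complemented for minus-strand
#' genes) and counts matches of each PWM at the relative-score threshold.
#' Overlapping matches are all counted.
#'
#' @param promoters `GRanges` from [define_promoters].
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param pwms named list of `PWM` objects.
#' @param min_similarity relative-score threshold (default 0.70).
#' @return Integer matrix promoters x PWMs, rownames = `gene_id`.
#' @export
count_matches <- function(promoters, genome, pwms, min_similarity = 0.70) {
  n <- length(promoters)
  m <- matrix(0L, n, length(pwms),
              dimnames = list(promoters$gene_id, names(pwms)))
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(promoters)[i])
    s <- subseq(genome[[chrom]], start(promoters)[i], end(promoters)[i])
    if (as.character(strand(promoters)[i]) == "-")
      s <- reverseComplement(s)
    for (k in seq_along(pwms))
      m[i, k] <- nrow(pwm_scan(s, pwms[[k]], min_similarity))
  }
  m
}

#' Binding-site enrichment of gene clusters over the promoter background
#'
#' For each PWM and cluster, the enrichment ratio is the mean number of
#' matches per promoter within the cluster divided by the genome-wide mean
#' matches per promoter. PWMs with a zero genome-wide mean yield `NA` and
#' are flagged.
#'
#' @param matches promoter x PWM match-count matrix from [count_matches]
#'   (rownames = gene ids).
#' @param clusters named vector, gene id -> cluster id (genes absent from
#'   `matches` are ignored).
#' @return list with `ratio` (cluster x PWM matrix), `background`
#'   (genome-wide mean per PWM), `flagged` (PWM ids with zero background).
#' @export
enrichment_matrix <- function(matches, clusters) {
  bg <- colMeans(matches)
  flagged <- colnames(matches)[bg == 0]
  clusters <- clusters[names(clusters) %in% rownames(matches)]
  cls <- sort(unique(clusters))
  ratio <- t(vapply(cls, function(ci) {
    genes <- names(clusters)[clusters == ci]
    colMeans(matches[genes, , drop = FALSE]) /
      ifelse(bg == 0, NA_real_, bg)
  }, numeric(ncol(matches))))
  rownames(ratio) <- as.character(cls)
  list(ratio = ratio, background = bg, flagged = flagged)
}
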