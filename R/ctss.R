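# CTSS handling: per-library 5'-end tag counts at single-base resolution.

#' Construct a CTSSMatrix
#'
#' Holds single-base, strand-specific CAGE-supported TSS (CTSS) positions
#' with an integer tag-count matrix over libraries. Library sizes (total
#' mapped tags) are fixed at construction and deliberately survive later
#' filtering, so that TPM normalization always uses total library tags.
#'
#' @param gr `GRanges` of width-1 positions (unique per chrom/position/strand).
#' @param counts integer matrix, rows matching `gr`, columns = libraries.
#' @param design data.frame with columns `library_id`, `genotype`,
#'   `timepoint`, `replicate`; one row per count column.
#' @param lib_sizes optional named totals; defaults to column sums.
#' @return An object of class `CTSSMatrix`.
#' @export
CTSSMatrix <- function(gr, counts, design, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is(gr, "GRanges"), all(width(gr) == 1L),
            length(gr) == nrow(counts), all(counts >= 0))
  stopifnot(all(c("library_id", "genotype", "timepoint", "replicate") %in%
                  names(design)))
  stopifnot(!anyDuplicated(design$library_id),
            ncol(counts) == nrow(design))
  colnames(counts) <- design$library_id
  key <- paste(seqnames(gr), start(gr), strand(gr))
  if (anyDuplicated(key)) stop("duplicate CTSS positions")
  o <- order(as.character(seqnames(gr)), start(gr), as.character(strand(gr)))
  gr <- gr[o]
  counts <- counts[o, , drop = FALSE]
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- setNames(as.numeric(lib_sizes), design$library_id)
  structure(list(gr = gr, counts = counts, design = design,
                 lib_sizes = lib_sizes),
            class = "CTSSMatrix")
}

#' @export
print.CTSSMatrix <- function(x, ...) {
  cat("CTSSMatrix:", length(x$gr), "positions x", ncol(x$counts),
      "libraries; total tags", sum(x$lib_sizes), "\n")
  invisible(x)
}

#' Read a sample design table
#'
#' @param path TSV with header `library_id`, `genotype`, `timepoint`,
#'   `replicate`.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("library_id", "genotype", "timepoint", "replicate") %in%
                  names(d)))
  if (anyDuplicated(d$library_id)) stop("duplicate library_id in design")
  d
}

read_ctss_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = numeric(0)))
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  colClasses = c("character", "integer", "integer",
                                 "character", "numeric", "character"))
  if (any(b$end - b$start != 1L))
    stop("CTSS BED records must be exactly 1 bp wide: ", path)
  data.frame(chrom = b$chrom, pos = b$start + 1L,  # BED is 0-based
             strand = b$strand, count = b$score,
             stringsAsFactors = FALSE)
}

#' Read per-library CTSS BED6 tracks into a CTSSMatrix
#'
#' One BED6 file per library; every record 1 bp wide, score = tag count,
#' strand in column 6. The matrix is assembled over the union of positions,
#' with zeros where a library has no tag.
#'
#' @param paths named character vector of BED paths, names = library ids.
#' @param design sample design data.frame (see [read_design]).
#' @return A [CTSSMatrix].
#' @export
read_ctss <- function(paths, design) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be named by library_id")
  unknown <- setdiff(names(paths), design$library_id)
  if (length(unknown))
    stop("library not in design: ", paste(unknown, collapse = ", "))
  missing <- setdiff(design$library_id, names(paths))
  if (length(missing))
    stop("design library without a CTSS file: ",
         paste(missing, collapse = ", "))
  tabs <- lapply(paths[design$library_id], read_ctss_bed)
  empty <- names(tabs)[vapply(tabs, nrow, integer(1)) == 0L]
  if (length(empty))
    warning("empty CTSS file for library: ", paste(empty, collapse = ", "))
  all_pos <- unique(do.call(rbind, lapply(tabs, function(t)
    t[c("chrom", "pos", "strand")])))
  if (nrow(all_pos) == 0L) stop("no CTSS records in any library")
  key <- paste(all_pos$chrom, all_pos$pos, all_pos$strand)
  counts <- matrix(0, nrow(all_pos), length(tabs),
                   dimnames = list(NULL, names(tabs)))
  for (j in seq_along(tabs)) {
    t <- tabs[[j]]
    if (!nrow(t)) next
    idx <- match(paste(t$chrom, t$pos, t$strand), key)
    counts[idx, j] <- counts[idx, j] + t$count
  }
  gr <- GRanges(all_pos$chrom, IRanges(all_pos$pos, width = 1L),
                strand = all_pos$strand)
  CTSSMatrix(gr, counts, design)
}

#' Write a CTSSMatrix as per-library BED6 files
#'
#' @param ctss a [CTSSMatrix].
#' @param dir output directory; files are named `<library_id>.ctss.bed`.
#' @return Named vector of written paths, invisibly.
#' @export
write_ctss <- function(ctss, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(ctss$design$library_id,
                                          ".ctss.bed")),
                    ctss$design$library_id)
  for (lib in ctss$design$library_id) {
    keep <- ctss$counts[, lib] > 0
    b <- data.frame(chrom = as.character(seqnames(ctss$gr))[keep],
                    start = start(ctss$gr)[keep] - 1L,
                    end = start(ctss$gr)[keep],
                    name = ".",
                    score = ctss$counts[keep, lib],
                    strand = as.character(strand(ctss$gr))[keep])
    write.table(b, paths[[lib]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Correct CTSS positions for the CAGE G-addition bias
#'
#' Reverse transcription of capped 5' ends adds a spurious G at the tag 5'
#' end; mapped CTSS coordinates are therefore shifted by `offset_bp` in the
#' direction of transcription (+ on the plus strand, - on the minus strand).
#' Counts landing on the same position after the shift are summed; positions
#' shifted below 1 are dropped with a warning.
#'
#' @param ctss a [CTSSMatrix].
#' @param offset_bp non-negative shift in bp (default 1).
#' @return A corrected [CTSSMatrix].
#' @export
apply_g_offset <- function(ctss, offset_bp = 1L) {
  stopifnot(offset_bp >= 0L)
  if (offset_bp == 0L) return(ctss)
  minus <- as.character(strand(ctss$gr)) == "-"
  newpos <- start(ctss$gr) + ifelse(minus, -offset_bp, offset_bp)
  keep <- newpos >= 1L
  if (any(!keep))
    warning(sum(!keep), " CTSS position(s) shifted below 1 were dropped")
  chrom <- as.character(seqnames(ctss$gr))[keep]
  str <- as.character(strand(ctss$gr))[keep]
  newpos <- newpos[keep]
  counts <- ctss$counts[keep, , drop = FALSE]
  key <- paste(chrom, newpos, str)
  grp <- match(key, unique(key))
  agg <- rowsum(counts, grp, reorder = TRUE)
  first <- !duplicated(key)
  gr <- GRanges(chrom[first], IRanges(newpos[first], width = 1L),
                strand = str[first])
  CTSSMatrix(gr, agg, ctss$design, lib_sizes = ctss$lib_sizes)
}
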