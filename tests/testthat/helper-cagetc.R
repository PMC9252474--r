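# Shared fixtures and independent brute-force oracles.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

mk_design <- function(n = 3L, genotypes = "wt", timepoints = 0L) {
  cells <- expand.grid(genotype = genotypes, timepoint = timepoints,
                       stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(nrow(cells)), each = n), ]
  d$replicate <- rep(seq_len(n), nrow(cells))
  d$library_id <- paste(d$genotype, d$timepoint, d$replicate, sep = "_")
  rownames(d) <- NULL
  d[c("library_id", "genotype", "timepoint", "replicate")]
}

# CTSSMatrix from a data.frame(pos, strand) and a count matrix
mk_ctss <- function(pos, strand, counts, chrom = "chr1", design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(design)) design <- mk_design(ncol(counts))
  CTSSMatrix(GRanges(chrom, IRanges(pos, width = 1L), strand = strand),
             counts, design)
}

# brute-force transitive-closure clustering of positions on one strand:
# two CTSSs are linked iff |p - q| <= max_dist; clusters are the
# connected components
bf_cluster <- function(pos, max_dist) {
  pos <- sort(pos)
  n <- length(pos)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= max_dist && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) range(pos[comp == cc]))
}

# per-base walk oracle: genomic positions of the spliced transcript in
# 5'->3' order
bf_spliced_positions <- function(exons) {
  exons <- sort(exons, ignore.strand = TRUE)
  pos <- unlist(lapply(seq_along(exons), function(i)
    start(exons)[i]:end(exons)[i]))
  if (as.character(strand(exons)[1]) == "-") rev(pos) else pos
}

# random multi-exon transcript on a random strand
random_transcript <- function(chrom = "chr1") {
  n_ex <- sample(2:5, 1)
  widths <- sample(20:200, n_ex, replace = TRUE)
  gaps <- sample(30:300, n_ex - 1, replace = TRUE)
  s <- sample(1000:50000, 1)
  starts <- s + cumsum(c(0, head(widths, -1) + gaps))
  GRanges(chrom, IRanges(starts, width = widths),
          strand = sample(c("+", "-"), 1))
}

# brute-force Benjamini-Hochberg step-up
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force PWM scan: enumerate every window on both strands
bf_pwm_scan <- function(seq_str, p, min_similarity = 0.70) {
  lo <- p$logodds
  w <- ncol(lo)
  rng <- p$score_range
  score1 <- function(sub) {
    idx <- match(strsplit(sub, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    s <- sum(lo[cbind(idx, seq_len(w))])
    (s - rng["min"]) / (rng["max"] - rng["min"])
  }
  n <- nchar(seq_str)
  out <- data.frame(start = integer(0), strand = character(0),
                    rel_score = numeric(0))
  if (n < w) return(out)
  rc <- as.character(reverseComplement(DNAString(seq_str)))
  for (i in 1:(n - w + 1)) {
    sc <- score1(substr(seq_str, i, i + w - 1))
    if (!is.na(sc) && sc >= min_similarity)
      out <- rbind(out, data.frame(start = i, strand = "+",
                                   rel_score = unname(sc)))
    scr <- score1(substr(rc, i, i + w - 1))
    if (!is.na(scr) && scr >= min_similarity)
      out <- rbind(out, data.frame(start = n - w + 2 - i, strand = "-",
                                   rel_score = unname(scr)))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# small deterministic annotation: two genes on opposite strands
# (plus-strand gene with leader/CDS/introns, minus-strand mirror)
toy_annotation <- function() {
  genes <- GRanges("chr1", IRanges(c(2001, 12001), c(4191, 14191)),
                   strand = c("+", "-"), gene_id = c("GP", "GM"))
  ex_p <- GRanges("chr1", IRanges(c(2001, 3151, 3802),
                                  c(2450, 3651, 4191)), strand = "+")
  cds_p <- GRanges("chr1", IRanges(c(2211, 3151, 3802),
                                   c(2450, 3651, 4041)), strand = "+")
  ex_m <- GRanges("chr1", IRanges(c(12001, 12541, 13742),
                                  c(12390, 13041, 14191)), strand = "-")
  cds_m <- GRanges("chr1", IRanges(c(12151, 12541, 13742),
                                   c(12390, 13041, 13981)), strand = "-")
  GenomeAnnotation(
    genes,
    data.frame(transcript_id = c("GP.1", "GM.1"),
               gene_id = c("GP", "GM")),
    GRangesList(GP.1 = ex_p, GM.1 = ex_m),
    GRangesList(GP.1 = cds_p, GM.1 = cds_m),
    seqlen = c(chr1 = 20000L))
}

# small fast simulation shared across tests
small_config <- function(seed = 7L, depth = 5e4, ...) {
  simulation_config(seed = seed, genome_length = 2e5L, n_genes = 30L,
                    n_switch_genes = 4L, n_uorf_skip_genes = 2L,
                    n_domain_disrupt_genes = 2L,
                    n_target_peptide_genes = 2L,
                    n_exosome_sensitive = 2L, n_deg_per_cluster = 2L,
                    n_enhancers = 4L, n_enhancers_intronic = 1L,
                    n_enhancers_induced = 1L, n_enhancers_exosome = 1L,
                    depth = depth, ...)
}

# memoized default-scale pipeline run (the reference study conditions)
.cagetc_cache <- new.env(parent = emptyenv())
default_run_cached <- function() {
  if (is.null(.cagetc_cache$default_run))
    .cagetc_cache$default_run <- run_pipeline(simulation_config(seed = 1L))
  .cagetc_cache$default_run
}
small_run_cached <- function() {
  if (is.null(.cagetc_cache$small_run))
    .cagetc_cache$small_run <- run_pipeline(small_config())
  .cagetc_cache$small_run
}
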