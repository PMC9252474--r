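# Synthetic CAGE experiment with planted ground truth: a genome, gene
# models with consequence side-tables, planted alternative TSSs and
# promoter switches, trajectory-assigned responsive genes,
# exosome-sensitive transcripts, bidirectional enhancer loci and promoter
# motifs -- plus the factorial CTSS libraries measuring all of it.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default genotype x timepoint CAGE design
#'
#' Wild type and the nucleoplasmic exosome mutant `hen2` at 0, 10 and 30
#' minutes of elicitor treatment, the core exosome mutant `rrp4` at 0 and
#' 30 minutes, each in biological triplicates (24 libraries).
#'
#' @param replicates replicates per cell (default 3).
#' @return Design data.frame (`library_id`, `genotype`, `timepoint`,
#'   `replicate`).
#' @export
default_design <- function(replicates = 3L) {
  cells <- rbind(expand.grid(genotype = c("wt", "hen2"),
                             timepoint = c(0L, 10L, 30L),
                             stringsAsFactors = FALSE),
                 expand.grid(genotype = "rrp4", timepoint = c(0L, 30L),
                             stringsAsFactors = FALSE))
  d <- cells[rep(seq_len(nrow(cells)), each = replicates), ]
  d$replicate <- rep(seq_len(replicates), nrow(cells))
  d$library_id <- paste(d$genotype, d$timepoint,
                        paste0("r", d$replicate), sep = "_")
  rownames(d) <- NULL
  d[c("library_id", "genotype", "timepoint", "replicate")]
}

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a 1-Mb
#' nuclear chromosome carrying 200 genes, a triplicated wt/hen2/rrp4 x
#' 0/10/30-min design, a depth of 500,000 tags per library,
#' negative-binomial count noise, 30 planted promoter switches, 10 genes
#' each with uORF-skipping, domain-disrupting and target-peptide-excluding
#' downstream TSSs, 10 exosome-sensitive transcripts, 10 responsive genes
#' in each of six trajectory shapes, and 20 bidirectional enhancer loci.
#'
#' @param seed RNG seed.
#' @param genome_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param design design data.frame (default [default_design]).
#' @param depth expected tags per library (library totals are held at this
#'   sequencing depth, so induced transcripts crowd out unchanged ones as
#'   in real libraries).
#' @param phi negative-binomial dispersion of per-TC counts (> 0).
#' @param decay geometric decay of CTSS positions around a TC peak.
#' @param footprint maximal offset (bp) of scattered positions from the
#'   peak on each side.
#' @param effect_size planted log2 effect of responsive trajectories.
#' @param exosome_effect planted log2 over-accumulation in exosome mutants.
#' @param minor_share fractional usage of the downstream (alternative) TC
#'   in planted multi-TC genes.
#' @param n_switch_genes,n_uorf_skip_genes,n_domain_disrupt_genes,n_target_peptide_genes
#'   planted feature counts.
#' @param n_exosome_sensitive exosome-sensitive single-TC genes.
#' @param n_deg_per_cluster responsive single-TC genes per trajectory
#'   shape (six shapes).
#' @param n_enhancers,n_enhancers_intronic enhancer loci (total, and how
#'   many placed inside introns).
#' @param n_enhancers_induced,n_enhancers_exosome enhancers with a planted
#'   t30 induction or exosome sensitivity.
#' @param enhancer_rate expected pooled (both-strand) enhancer tags per
#'   library before depth normalization.
#' @param enhancer_balance expected minus-strand fraction of enhancer
#'   signal (0.5 = balanced).
#' @param n_pwms synthetic motif matrices emitted; the first is planted in
#'   the promoters of cluster `motif_cluster` genes.
#' @param motif_cluster trajectory cluster receiving the planted motif.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 1e6L,
                              n_genes = 200L,
                              design = default_design(),
                              depth = 5e5,
                              phi = 0.1,
                              decay = 0.6,
                              footprint = 10L,
                              effect_size = 3,
                              exosome_effect = 2,
                              minor_share = 0.3,
                              n_switch_genes = 30L,
                              n_uorf_skip_genes = 10L,
                              n_domain_disrupt_genes = 10L,
                              n_target_peptide_genes = 10L,
                              n_exosome_sensitive = 10L,
                              n_deg_per_cluster = 10L,
                              n_enhancers = 20L,
                              n_enhancers_intronic = 4L,
                              n_enhancers_induced = 5L,
                              n_enhancers_exosome = 5L,
                              enhancer_rate = 50,
                              enhancer_balance = 0.5,
                              n_pwms = 5L,
                              motif_cluster = 5L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_switch_genes, cfg$n_uorf_skip_genes,
              cfg$n_domain_disrupt_genes, cfg$n_target_peptide_genes,
              cfg$n_exosome_sensitive, cfg$n_deg_per_cluster,
              cfg$n_enhancers, cfg$n_enhancers_intronic, cfg$n_pwms)
  stopifnot(all(counts >= 0), cfg$phi > 0, cfg$decay > 0, cfg$decay < 1,
            cfg$minor_share > 0, cfg$minor_share < 1,
            cfg$enhancer_balance >= 0, cfg$enhancer_balance <= 1,
            cfg$n_enhancers_intronic <= cfg$n_enhancers,
            cfg$n_enhancers_induced + cfg$n_enhancers_exosome <=
              cfg$n_enhancers)
  n_planted <- cfg$n_switch_genes + cfg$n_uorf_skip_genes +
    cfg$n_domain_disrupt_genes + cfg$n_target_peptide_genes +
    cfg$n_exosome_sensitive + 6L * cfg$n_deg_per_cluster
  if (n_planted + cfg$n_enhancers_intronic > cfg$n_genes)
    stop("n_genes too small for the requested planted features (need >= ",
         n_planted + cfg$n_enhancers_intronic, ")")
  class(cfg) <- "simulation_config"
  cfg
}

# log2 trajectory multiplier per timepoint for the six shapes
# (C1 late-up, C2 early-sustained-up, C5 transient-up; C3/C4/C6 mirrored)
traj_log2 <- function(shape, timepoint, e) {
  dev <- switch(shape,
                C1 = c(`0` = 0, `10` = 0, `30` = e),
                C2 = c(`0` = 0, `10` = e, `30` = e),
                C5 = c(`0` = 0, `10` = e, `30` = 0),
                C3 = c(`0` = 0, `10` = 0, `30` = -e),
                C4 = c(`0` = 0, `10` = -e, `30` = -e),
                C6 = c(`0` = 0, `10` = -e, `30` = 0),
                SW_UP = c(`0` = 0, `10` = 0, `30` = e),
                SW_DN = c(`0` = 0, `10` = 0, `30` = -e),
                flat = c(`0` = 0, `10` = 0, `30` = 0),
                stop("unknown trajectory shape: ", shape))
  unname(dev[as.character(timepoint)])
}

# gene architecture (widths 5'->3'); CDS = 240 + 501 + 240 = 981 nt
GENE_LEADER <- 210L
GENE_EX1 <- 450L
GENE_EX2 <- 501L
GENE_IN2 <- 150L
GENE_EX3 <- 390L
GENE_CDS3 <- 240L   # CDS part of exon 3; remainder is 3' UTR
SAFE_CODONS <- c("GCT", "GCC", "AAG", "GAA", "CTT", "TCT")

gene_span <- function(intron1) GENE_EX1 + intron1 + GENE_EX2 + GENE_IN2 +
  GENE_EX3

# transcript position -> genomic, for the fixed architecture
arch_tx_to_genome <- function(start, end, strand, intron1, tx_pos) {
  w <- c(GENE_EX1, GENE_EX2, GENE_EX3)
  cs <- cumsum(w)
  gaps <- c(0L, intron1, intron1 + GENE_IN2)
  i <- findInterval(tx_pos - 1L, c(0L, cs))
  off <- tx_pos + gaps[i]          # offset from the transcript 5' base
  if (strand == "+") start + off - 1L else end - off + 1L
}

empty_truth <- function()
  data.frame(kind = character(0), id = character(0),
             gene_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             peak_primary = integer(0), peak_alt = integer(0),
             class = character(0), cluster = integer(0),
             contrast = character(0), effect_log2 = numeric(0))

empty_tc_truth <- function()
  data.frame(gene_id = character(0), tc = integer(0), peak = integer(0),
             strand = character(0), share = numeric(0),
             base_share = numeric(0), shape = character(0),
             exosome = logical(0))

#' Simulate a genome with planted features
#'
#' Lays out non-overlapping three-exon gene models on alternating strands,
#' assigns planted roles (promoter switches, uORF-skipping /
#' domain-disrupting / target-peptide-excluding downstream TSSs,
#' exosome-sensitive transcripts, six-shape responsive genes), places
#' bidirectional enhancer loci in intergenic gaps and introns, writes the
#' planted uORF and promoter-motif sequences into the genome, and records
#' everything in a machine-readable truth table.
#'
#' @param config a [simulation_config].
#' @return list with `genome` (`DNAStringSet`), `ann`
#'   ([GenomeAnnotation]), `truth` (data.frame), `tc_truth` and
#'   `enh_truth` (per-TC / per-enhancer layout used by [simulate_ctss]),
#'   `pwms`, `config`.
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(is(config, "simulation_config"))
  chrom <- "chr1"
  L <- as.integer(config$genome_length)
  if (config$n_genes == 0L) {
    genome <- with_seed(config$seed, {
      DNAStringSet(setNames(paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE),
                                  collapse = ""), chrom))
    })
    empty_genes <- GRanges()
    mcols(empty_genes)$gene_id <- character(0)
    ann <- GenomeAnnotation(
      empty_genes,
      data.frame(transcript_id = character(0), gene_id = character(0)),
      GRangesList(), seqlen = setNames(L, chrom))
    return(list(genome = genome, ann = ann, truth = empty_truth(),
                tc_truth = empty_tc_truth(), enh_truth = NULL,
                pwms = list(), config = config))
  }
  with_seed(config$seed, {
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # planted roles, shuffled over gene indices
    roles <- c(rep("switch", config$n_switch_genes),
               rep("uorf", config$n_uorf_skip_genes),
               rep("domain", config$n_domain_disrupt_genes),
               rep("tpep", config$n_target_peptide_genes),
               rep("exosome", config$n_exosome_sensitive),
               rep(paste0("deg_C", 1:6), each = config$n_deg_per_cluster),
               rep("plain", config$n_genes - config$n_switch_genes -
                     config$n_uorf_skip_genes -
                     config$n_domain_disrupt_genes -
                     config$n_target_peptide_genes -
                     config$n_exosome_sensitive -
                     6L * config$n_deg_per_cluster))
    roles <- sample(roles)
    # gene baselines (log-normal share of depth); the minor-TC share
    # shrinks with expression rank, mirroring the observed decline of
    # alternative-TSS usage in highly expressed genes
    base_w <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
    base_share <- base_w / sum(base_w)
    expr_q <- (rank(base_share) - 1) / max(config$n_genes - 1, 1)
    minor_share_g <- config$minor_share * (1 - 0.4 * expr_q)
    intronic_hosts <- head(which(roles == "plain"),
                           config$n_enhancers_intronic)
    if (length(intronic_hosts) < config$n_enhancers_intronic)
      stop("not enough plain genes to host intronic enhancers")

    # layout: genes left to right, intergenic enhancer slots interleaved
    n_intergenic_enh <- config$n_enhancers - config$n_enhancers_intronic
    enh_before <- if (n_intergenic_enh > 0)
      unique(round(seq(1, config$n_genes, length.out = n_intergenic_enh)))
    else integer(0)
    if (length(enh_before) < n_intergenic_enh)
      stop("n_genes too small to interleave ", n_intergenic_enh,
           " intergenic enhancers")
    intron1 <- ifelse(seq_len(config$n_genes) %in% intronic_hosts,
                      900L, 700L)
    gaps <- 600L + sample(0:400, config$n_genes, replace = TRUE)
    cursor <- 1001L
    gene_start <- integer(config$n_genes)
    enh_mid <- integer(0)
    enh_context <- character(0)
    for (i in seq_len(config$n_genes)) {
      if (i %in% enh_before) {
        enh_mid <- c(enh_mid, cursor + 800L)
        enh_context <- c(enh_context, "intergenic")
        cursor <- cursor + 1600L
      }
      gene_start[i] <- cursor
      cursor <- cursor + gene_span(intron1[i]) + gaps[i]
    }
    if (cursor + 1000L > L)
      stop("genome_length too small for ", config$n_genes,
           " genes; need at least ", cursor + 1000L, " bp")

    gene_id <- sprintf("G%04d", seq_len(config$n_genes))
    tx_id <- paste0(gene_id, ".1")
    strands <- rep(c("+", "-"), length.out = config$n_genes)
    gene_end <- gene_start + gene_span(intron1) - 1L

    # exon/CDS coordinates, vectorized over genes (5'->3' widths:
    # exon1 = leader+CDS, intron1, exon2 = CDS, intron2, exon3 = CDS+3'UTR)
    ex_off5 <- rbind(0L, GENE_EX1 + intron1, GENE_EX1 + intron1 +
                       GENE_EX2 + GENE_IN2)       # 3 x n, 5' offsets
    ex_w <- c(GENE_EX1, GENE_EX2, GENE_EX3)
    plus <- strands == "+"
    ex_start <- ex_end <- matrix(0L, 3, config$n_genes)
    for (j in 1:3) {
      ex_start[j, plus] <- gene_start[plus] + ex_off5[j, plus]
      ex_end[j, plus] <- ex_start[j, plus] + ex_w[j] - 1L
      ex_end[j, !plus] <- gene_end[!plus] - ex_off5[j, !plus]
      ex_start[j, !plus] <- ex_end[j, !plus] - ex_w[j] + 1L
    }
    # CDS pieces in transcript order: exon1 minus leader, exon2, CDS3
    cds_start <- cds_end <- matrix(0L, 3, config$n_genes)
    cds_start[1, plus] <- ex_start[1, plus] + GENE_LEADER
    cds_end[1, plus] <- ex_end[1, plus]
    cds_start[1, !plus] <- ex_start[1, !plus]
    cds_end[1, !plus] <- ex_end[1, !plus] - GENE_LEADER
    cds_start[2, ] <- ex_start[2, ]
    cds_end[2, ] <- ex_end[2, ]
    cds_start[3, plus] <- ex_start[3, plus]
    cds_end[3, plus] <- ex_start[3, plus] + GENE_CDS3 - 1L
    cds_end[3, !plus] <- ex_end[3, !plus]
    cds_start[3, !plus] <- ex_end[3, !plus] - GENE_CDS3 + 1L

    tx_fac <- factor(rep(tx_id, each = 3L), levels = tx_id)
    exons_by_tx <- split(GRanges(chrom, IRanges(as.vector(ex_start),
                                                as.vector(ex_end)),
                                 strand = rep(strands, each = 3L)),
                         tx_fac)
    cds_by_tx <- split(GRanges(chrom, IRanges(as.vector(cds_start),
                                              as.vector(cds_end)),
                               strand = rep(strands, each = 3L)),
                       tx_fac)
    genes <- GRanges(chrom, IRanges(gene_start, gene_end),
                     strand = strands, gene_id = gene_id)

    # intronic enhancer midpoints: center of the widened first intron
    for (i in intronic_hosts) {
      ilo <- if (plus[i]) ex_end[1, i] + 1L else ex_end[2, i] + 1L
      ihi <- if (plus[i]) ex_start[2, i] - 1L else ex_start[1, i] - 1L
      enh_mid <- c(enh_mid, as.integer((ilo + ihi) %/% 2))
      enh_context <- c(enh_context, "intronic")
    }

    # planted TC layout; transcript positions of the alternative TCs:
    # switch -> CDS (exon 2), domain/tpep -> within/after the planted
    # feature (exon 2), uorf -> leader, downstream of the planted uORF
    tss <- ifelse(plus, gene_start, gene_end)
    alt_tx_pos <- c(switch = 700L, domain = 610L, tpep = 610L,
                    uorf = 170L)
    tc_rows <- list()
    truth_rows <- list()
    dom_list <- list(); tpep_list <- list(); uorf_list <- list()
    for (i in seq_len(config$n_genes)) {
      role <- roles[i]
      shape1 <- "flat"; shape2 <- NA_character_
      exo <- role == "exosome"
      alt_peak <- NA_integer_
      class <- NA_character_
      cluster <- NA_integer_
      kind <- "plain"
      if (role == "switch") {
        shape1 <- "SW_DN"; shape2 <- "SW_UP"; kind <- "switch"
        class <- "none"
      } else if (role == "domain") {
        shape2 <- "C1"; kind <- "domain_disrupt"
        class <- "domain_disruptive"
        dom_list[[length(dom_list) + 1L]] <-
          data.frame(transcript_id = tx_id[i], aa_start = 40L,
                     aa_end = 200L, label = "DOM1")
      } else if (role == "tpep") {
        shape2 <- "C1"; kind <- "target_peptide"
        class <- "target_peptide_excluding"
        tpep_list[[length(tpep_list) + 1L]] <-
          data.frame(transcript_id = tx_id[i], cleavage_aa = 60L,
                     kind = "plastid")
      } else if (role == "uorf") {
        shape2 <- "C1"; kind <- "uorf_skip"
        class <- "uorf_skipping"
        uorf_list[[length(uorf_list) + 1L]] <-
          data.frame(transcript_id = tx_id[i], tx_start = 61L,
                     tx_end = 120L)
      } else if (startsWith(role, "deg_")) {
        shape1 <- sub("deg_", "", role)
        cluster <- as.integer(sub("deg_C", "", role))
        kind <- "deg_cluster"
      } else if (exo) {
        kind <- "exosome"
      }
      if (role %in% names(alt_tx_pos))
        alt_peak <- arch_tx_to_genome(gene_start[i], gene_end[i],
                                      strands[i], intron1[i],
                                      alt_tx_pos[[role]])
      has_alt <- !is.na(alt_peak)
      tc_rows[[i]] <- data.frame(
        gene_id = gene_id[i],
        tc = if (has_alt) c(1L, 2L) else 1L,
        peak = if (has_alt) c(tss[i], alt_peak) else tss[i],
        strand = strands[i],
        share = if (has_alt) c(1 - minor_share_g[i], minor_share_g[i])
                else 1,
        base_share = base_share[i],
        shape = if (has_alt) c(shape1, shape2) else shape1,
        exosome = exo,
        stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        kind = kind, id = gene_id[i], gene_id = gene_id[i], chrom = chrom,
        start = gene_start[i], end = gene_end[i], strand = strands[i],
        peak_primary = tss[i], peak_alt = alt_peak,
        class = class, cluster = cluster,
        contrast = if (exo) "genotype"
                   else if (has_alt || startsWith(role, "deg_")) "t30"
                   else NA_character_,
        effect_log2 = if (role == "plain") 0
                      else if (exo) config$exosome_effect
                      else config$effect_size,
        stringsAsFactors = FALSE)
    }
    tc_truth <- do.call(rbind, tc_rows)
    truth <- do.call(rbind, truth_rows)
    truth <- truth[truth$kind != "plain", , drop = FALSE]
    domains <- if (length(dom_list)) do.call(rbind, dom_list) else NULL
    tpeps <- if (length(tpep_list)) do.call(rbind, tpep_list) else NULL
    uorfs <- if (length(uorf_list)) do.call(rbind, uorf_list) else NULL

    # enhancer truth: trajectory roles over the locus list
    n_enh <- length(enh_mid)
    enh_shape <- rep("flat", n_enh)
    if (config$n_enhancers_induced > 0)
      enh_shape[seq_len(config$n_enhancers_induced)] <- "C1"
    enh_exo <- rep(FALSE, n_enh)
    if (config$n_enhancers_exosome > 0)
      enh_exo[config$n_enhancers_induced +
                seq_len(config$n_enhancers_exosome)] <- TRUE
    enh_id <- sprintf("E%03d", seq_len(n_enh))
    if (n_enh > 0)
      truth <- rbind(truth, data.frame(
        kind = "enhancer", id = enh_id, gene_id = NA_character_,
        chrom = chrom, start = enh_mid, end = enh_mid, strand = "*",
        peak_primary = enh_mid, peak_alt = NA_integer_,
        class = enh_context, cluster = NA_integer_,
        contrast = ifelse(enh_shape == "C1", "t30",
                          ifelse(enh_exo, "genotype", NA_character_)),
        effect_log2 = ifelse(enh_shape == "C1", config$effect_size,
                             ifelse(enh_exo, config$exosome_effect, 0)),
        stringsAsFactors = FALSE))
    enh_truth <- data.frame(id = enh_id, mid = enh_mid,
                            context = enh_context, shape = enh_shape,
                            exosome = enh_exo, stringsAsFactors = FALSE)

    # write planted uORF sequences into the leaders (exon 1 is contiguous
    # there, so transcript positions map to a genomic run)
    if (!is.null(uorfs)) {
      for (j in seq_len(nrow(uorfs))) {
        i <- match(uorfs$transcript_id[j], tx_id)
        seq_str <- paste0("ATG", paste(sample(SAFE_CODONS, 18L,
                                              replace = TRUE),
                                       collapse = ""), "TAA")
        b <- strsplit(seq_str, "")[[1]]
        if (plus[i]) {
          at <- gene_start[i] + (uorfs$tx_start[j] - 1L)
          bases[at:(at + 59L)] <- b
        } else {
          at <- gene_end[i] - (uorfs$tx_start[j] - 1L)
          bases[(at - 59L):at] <- rev(chartr("ACGT", "TGCA", b))
        }
      }
    }

    # synthetic PWMs; the first is planted into the promoters of the
    # motif_cluster responsive genes, 60 bp upstream of the annotated TSS
    pwms <- list()
    motif_w <- 12L
    consensus <- character(config$n_pwms)
    for (k in seq_len(config$n_pwms)) {
      cons <- paste(sample(c("A", "C", "G", "T"), motif_w,
                           replace = TRUE), collapse = "")
      consensus[k] <- cons
      m <- matrix(2, 4, motif_w, dimnames = list(BASES, NULL))
      m[cbind(match(strsplit(cons, "")[[1]], BASES),
              seq_len(motif_w))] <- 94
      id <- sprintf("M%02d", k)
      pwms[[id]] <- pwm(id, m, name = paste0("motif", k))
    }
    if (config$n_pwms > 0 && config$n_deg_per_cluster > 0) {
      targets <- which(roles == paste0("deg_C", config$motif_cluster))
      cb <- strsplit(consensus[1], "")[[1]]
      for (i in targets) {
        if (plus[i])
          bases[(tss[i] - 60L):(tss[i] - 60L + motif_w - 1L)] <- cb
        else
          bases[(tss[i] + 60L - motif_w + 1L):(tss[i] + 60L)] <-
            rev(chartr("ACGT", "TGCA", cb))
      }
      truth <- rbind(truth, data.frame(
        kind = "motif", id = names(pwms)[1], gene_id = NA_character_,
        chrom = chrom, start = NA_integer_, end = NA_integer_,
        strand = "*", peak_primary = NA_integer_, peak_alt = NA_integer_,
        class = NA_character_, cluster = config$motif_cluster,
        contrast = NA_character_, effect_log2 = NA_real_,
        stringsAsFactors = FALSE))
    }

    genome <- DNAStringSet(setNames(paste(bases, collapse = ""), chrom))
    ann <- GenomeAnnotation(
      genes,
      data.frame(transcript_id = tx_id, gene_id = gene_id,
                 stringsAsFactors = FALSE),
      exons_by_tx, cds_by_tx,
      domains = domains, target_peptides = tpeps, uorfs = uorfs,
      seqlen = setNames(L, chrom))
    list(genome = genome, ann = ann, truth = truth,
         tc_truth = tc_truth, enh_truth = enh_truth, pwms = pwms,
         config = config)
  })
}

#' Simulate the CTSS libraries of a planted experiment
#'
#' Per library, each planted TC's expected count is proportional to
#' `gene baseline share x TC share x 2^trajectory(genotype, timepoint)`,
#' with exosome-sensitive TCs additionally multiplied in the
#' exosome-mutant genotypes; expected totals are then rescaled so every
#' library sequences `depth` tags (induced transcripts crowd out
#' unchanged ones, as under fixed sequencing depth). Observed totals are
#' negative binomial with dispersion `phi`; tags are scattered around the
#' TC peak with geometric positional decay within `footprint` bp.
#' Enhancer loci emit divergent signal: minus-strand tags just upstream
#' and plus-strand tags just downstream of the midpoint, split by the
#' configured balance.
#'
#' @param sim result of [simulate_genome].
#' @param dir optional directory; when given, per-library BED6 CTSS files
#'   and a design TSV are written there.
#' @return A [CTSSMatrix].
#' @export
simulate_ctss <- function(sim, dir = NULL) {
  config <- sim$config
  if (config$depth <= 0) stop("library depth must be positive")
  design <- config$design
  nlib <- nrow(design)
  tct <- sim$tc_truth
  et <- sim$enh_truth
  with_seed(config$seed + 1L, {
    tp <- design$timepoint
    exo_lib <- design$genotype %in% c("hen2", "rrp4")

    # expected counts per emission unit (TCs, then enhancer halves)
    units <- list()
    for (r in seq_len(nrow(tct))) {
      lg2 <- vapply(seq_len(nlib), function(l)
        traj_log2(tct$shape[r], tp[l], config$effect_size), numeric(1))
      if (tct$exosome[r]) lg2 <- lg2 + config$exosome_effect * exo_lib
      units[[length(units) + 1L]] <- list(
        center = tct$peak[r], strand = tct$strand[r],
        mu = tct$base_share[r] * tct$share[r] * config$depth * 2^lg2)
    }
    if (!is.null(et) && nrow(et)) {
      for (r in seq_len(nrow(et))) {
        lg2 <- vapply(seq_len(nlib), function(l)
          traj_log2(et$shape[r], tp[l], config$effect_size), numeric(1))
        if (et$exosome[r]) lg2 <- lg2 + config$exosome_effect * exo_lib
        mu <- config$enhancer_rate * 2^lg2
        units[[length(units) + 1L]] <- list(
          center = et$mid[r] - 25L, strand = "-",
          mu = mu * config$enhancer_balance)
        units[[length(units) + 1L]] <- list(
          center = et$mid[r] + 25L, strand = "+",
          mu = mu * (1 - config$enhancer_balance))
      }
    }
    if (!length(units)) stop("nothing to simulate")

    # fixed sequencing depth: rescale expected totals per library
    mu_mat <- do.call(rbind, lapply(units, `[[`, "mu"))
    scale <- config$depth / colSums(mu_mat)
    mu_mat <- sweep(mu_mat, 2, scale, "*")

    offs <- -config$footprint:config$footprint
    wpos <- config$decay^abs(offs)
    wpos <- wpos / sum(wpos)
    pos_list <- list(); str_list <- list(); cnt_list <- list()
    for (u in seq_along(units)) {
      cnt <- matrix(0, length(offs), nlib)
      for (l in seq_len(nlib)) {
        tot <- rnbinom(1L, size = 1 / config$phi, mu = mu_mat[u, l])
        if (tot > 0) cnt[, l] <- rmultinom(1L, tot, wpos)
      }
      keep <- rowSums(cnt) > 0
      if (!any(keep)) next
      k <- length(pos_list) + 1L
      pos_list[[k]] <- units[[u]]$center + offs[keep]
      str_list[[k]] <- rep(units[[u]]$strand, sum(keep))
      cnt_list[[k]] <- cnt[keep, , drop = FALSE]
    }
    if (!length(pos_list)) stop("simulation produced no tags")
    gr <- GRanges(names(sim$ann$seqlen)[1],
                  IRanges(unlist(pos_list), width = 1L),
                  strand = unlist(str_list))
    counts <- do.call(rbind, cnt_list)
    ctss <- CTSSMatrix(gr, counts, design)
    if (!is.null(dir)) {
      write_ctss(ctss, dir)
      write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    ctss
  })
}

#' Read a simulation configuration from YAML
#'
#' The file holds any subset of [simulation_config]'s arguments as
#' top-level keys; a `design` key may name a TSV file (read with
#' [read_design]) instead of inlining the table.
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$design) && is.character(cfg$design))
    cfg$design <- read_design(cfg$design)
  do.call(simulation_config, cfg)
}

#' Simulate a complete planted CAGE experiment
#'
#' Runs [simulate_genome] and [simulate_ctss]; optionally writes every
#' artifact (FASTA, GFF3, side tables, truth table, JASPAR motifs, design
#' and per-library CTSS BED files) to `dir`.
#'
#' @param config a [simulation_config].
#' @param dir optional output directory.
#' @return list with `genome`, `ann`, `truth`, `tc_truth`, `enh_truth`,
#'   `pwms`, `ctss`, `config`.
#' @export
simulate_experiment <- function(config = simulation_config(), dir = NULL) {
  sim <- simulate_genome(config)
  sim$ctss <- simulate_ctss(sim, dir = if (is.null(dir)) NULL
                                       else file.path(dir, "ctss"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    write_gff3(sim$ann, file.path(dir, "annotation.gff3"))
    wt <- function(d, f) if (!is.null(d))
      write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(sim$ann$domains, "domains.tsv")
    wt(sim$ann$target_peptides, "target_peptides.tsv")
    wt(sim$ann$uorfs, "uorfs.tsv")
    wt(sim$truth, "truth.tsv")
    if (length(sim$pwms))
      write_jaspar(sim$pwms, file.path(dir, "pwms.jaspar"))
  }
  sim
}
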