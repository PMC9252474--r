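# Simulator determinism, feasibility checks and planted-signal fidelity.

test_that("identical seeds reproduce the experiment; seeds matter", {
  cfg <- small_config(seed = 3L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$ctss$counts, b$ctss$counts)
  c <- simulate_experiment(small_config(seed = 4L))
  expect_false(identical(a$ctss$counts, c$ctss$counts))
})

test_that("simulation files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(small_config(seed = 5L), dir = dir)
  ann2 <- read_gff3(file.path(dir, "annotation.gff3"))
  expect_equal(length(ann2$genes), length(sim$ann$genes))
  expect_identical(as.data.frame(ann2$genes), as.data.frame(sim$ann$genes))
  design <- read_design(file.path(dir, "ctss", "design.tsv"))
  paths <- setNames(file.path(dir, "ctss",
                              paste0(design$library_id, ".ctss.bed")),
                    design$library_id)
  ctss2 <- read_ctss(paths, design)
  expect_equal(unname(ctss2$lib_sizes), unname(sim$ctss$lib_sizes))
  pw <- read_jaspar(file.path(dir, "pwms.jaspar"))
  expect_equal(names(pw), names(sim$pwms))
  genome2 <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome2[[1]]), as.character(sim$genome[[1]]))
})

test_that("degenerate configurations are rejected or handled", {
  expect_error(simulation_config(n_genes = 10L), "n_genes too small")
  cfg <- small_config()
  cfg$genome_length <- 5e4L
  expect_error(simulate_genome(cfg), "at least")
  sim <- simulate_genome(simulation_config(
    n_genes = 0L, genome_length = 1e4L, n_switch_genes = 0L,
    n_uorf_skip_genes = 0L, n_domain_disrupt_genes = 0L,
    n_target_peptide_genes = 0L, n_exosome_sensitive = 0L,
    n_deg_per_cluster = 0L, n_enhancers = 0L, n_enhancers_intronic = 0L,
    n_enhancers_induced = 0L, n_enhancers_exosome = 0L))
  expect_equal(length(sim$ann$genes), 0L)
  expect_equal(Biostrings::width(sim$genome), 10000L)
  sim$config$depth <- 0
  expect_error(simulate_ctss(sim), "depth")
})

test_that("YAML configurations map onto simulation_config", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "genome_length: 50000", "n_genes: 4",
               "n_switch_genes: 1", "n_uorf_skip_genes: 0",
               "n_domain_disrupt_genes: 0", "n_target_peptide_genes: 0",
               "n_exosome_sensitive: 0", "n_deg_per_cluster: 0",
               "n_enhancers: 1", "n_enhancers_intronic: 0",
               "n_enhancers_induced: 0", "n_enhancers_exosome: 0",
               "depth: 1000"), p)
  cfg <- read_simulation_config(p)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$n_genes, 4)
  writeLines(c("seed: 9", "bogus_key: 1"), p)
  expect_error(read_simulation_config(p), "bogus_key")
})

test_that("planted enhancers sit in the annotated context", {
  sim <- simulate_genome(small_config(seed = 6L))
  enh <- sim$truth[sim$truth$kind == "enhancer", ]
  expect_equal(nrow(enh), 4L)
  mids <- GRanges(enh$chrom, IRanges(enh$start, width = 1L))
  in_gene <- overlapsAny(mids, sim$ann$genes, ignore.strand = TRUE)
  expect_equal(enh$class == "intronic", in_gene)
  all_ex <- unlist(sim$ann$exons_by_tx, use.names = FALSE)
  expect_false(any(overlapsAny(mids, all_ex, ignore.strand = TRUE)))
})

test_that("every planted feature leaves signal in the emitted tracks", {
  sim <- simulate_experiment(small_config(seed = 8L))
  pooled <- rowSums(sim$ctss$counts)
  pos <- start(sim$ctss$gr)
  near_signal <- function(at) any(abs(pos - at) <= 25 & pooled > 0)
  for (i in seq_len(nrow(sim$tc_truth)))
    expect_true(near_signal(sim$tc_truth$peak[i]))
  for (m in sim$enh_truth$mid)
    expect_true(near_signal(m))
})

test_that("library totals honour the configured sequencing depth", {
  sim <- simulate_experiment(small_config(seed = 9L))
  expect_lt(max(abs(sim$ctss$lib_sizes - sim$config$depth)) /
              sim$config$depth, 0.25)
})

test_that("counts approach their expectation as dispersion vanishes", {
  cfg <- small_config(seed = 10L, phi = 1e-3, depth = 1e6)
  sim <- simulate_experiment(cfg)
  # expected per-TC, per-library means recomputed from the truth tables
  tct <- sim$tc_truth
  et <- sim$enh_truth
  d <- cfg$design
  lg2 <- function(shape, exo) {
    v <- vapply(seq_len(nrow(d)), function(l)
      cagetc:::traj_log2(shape, d$timepoint[l], cfg$effect_size),
      numeric(1))
    if (exo) v <- v + cfg$exosome_effect *
        (d$genotype %in% c("hen2", "rrp4"))
    v
  }
  mu_tc <- t(vapply(seq_len(nrow(tct)), function(r)
    tct$base_share[r] * tct$share[r] * cfg$depth *
      2^lg2(tct$shape[r], tct$exosome[r]), numeric(nrow(d))))
  mu_enh <- t(vapply(seq_len(nrow(et)), function(r)
    cfg$enhancer_rate * 2^lg2(et$shape[r], et$exosome[r]),
    numeric(nrow(d))))
  scale <- cfg$depth / colSums(rbind(mu_tc, mu_enh))
  expected <- rowSums(sweep(mu_tc, 2, scale, "*"))

  pooled <- rowSums(sim$ctss$counts)
  pos <- start(sim$ctss$gr)
  str <- as.character(strand(sim$ctss$gr))
  obs <- vapply(seq_len(nrow(tct)), function(r)
    sum(pooled[abs(pos - tct$peak[r]) <= cfg$footprint &
                 str == tct$strand[r]]), numeric(1))
  keep <- expected > 2000          # law-of-large-numbers regime
  rel <- abs(obs - expected)[keep] / expected[keep]
  expect_lt(mean(rel), 0.05)
})

test_that("balanced enhancers split tags evenly between strands", {
  sim <- simulate_experiment(small_config(seed = 12L))
  pos <- start(sim$ctss$gr)
  str <- as.character(strand(sim$ctss$gr))
  pooled <- rowSums(sim$ctss$counts)
  for (m in sim$enh_truth$mid) {
    u <- sum(pooled[pos >= m - 250 & pos < m & str == "-"])
    d <- sum(pooled[pos >= m & pos < m + 250 & str == "+"])
    tot <- u + d
    # binomial 99.9% interval around 0.5
    half <- 3.3 * sqrt(0.25 / tot)
    expect_lt(abs(u / tot - 0.5), half + 0.02)
  }
})

test_that("planted uORF sequences are present and scannable", {
  sim <- simulate_genome(small_config(seed = 13L))
  for (j in seq_len(nrow(sim$ann$uorfs))) {
    tx <- sim$ann$uorfs$transcript_id[j]
    ex <- sim$ann$exons_by_tx[[tx]]
    walk <- bf_spliced_positions(ex)
    leader <- paste(vapply(walk[1:210], function(p) {
      b <- substr(as.character(sim$genome[[1]]), p, p)
      b
    }, character(1)), collapse = "")
    if (as.character(strand(ex)[1]) == "-")
      leader <- chartr("ACGT", "TGCA", leader)
    u <- scan_uorfs(leader)
    expect_true(any(u$tx_start == sim$ann$uorfs$tx_start[j] &
                      u$tx_end == sim$ann$uorfs$tx_end[j]))
  }
})
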