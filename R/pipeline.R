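# End-to-end orchestration: simulate -> cluster -> annotate -> DE/DTU/
# switches -> consequences -> enhancers -> TFBS enrichment, with a
# deterministic summary and a truth-vs-called comparison.

#' Aggregate TC expression to gene level
#'
#' Sums TC counts per assigned host gene (all intragenic TCs, before the
#' contribution gate) and renormalizes to tags per million of the total
#' library size.
#'
#' @param tcset a `TagClusterSet`.
#' @param assign data.frame from [assign_and_filter_intragenic].
#' @return list with `counts` and `tpm` (gene x library matrices).
#' @export
gene_expression <- function(tcset, assign) {
  idx <- which(!is.na(assign$gene_id))
  grp <- assign$gene_id[idx]
  counts <- rowsum(tcset$counts[idx, , drop = FALSE], grp)
  denom <- ifelse(tcset$lib_sizes == 0, Inf, tcset$lib_sizes)
  tpm <- sweep(counts, 2, denom, "/") * 1e6
  list(counts = counts, tpm = tpm)
}

match_positions <- function(called, truth, tol) {
  if (!length(truth)) return(list(sens = NA_real_, prec = NA_real_,
                                  matched = 0L))
  hit_truth <- vapply(truth, function(m)
    any(abs(called - m) <= tol), logical(1))
  hit_called <- if (length(called))
    vapply(called, function(m) any(abs(truth - m) <= tol), logical(1))
  else logical(0)
  list(sens = mean(hit_truth),
       prec = if (length(called)) mean(hit_called) else NA_real_,
       matched = sum(hit_truth))
}

#' Compare pipeline calls with the simulator's truth table
#'
#' @param res result list from [run_pipeline].
#' @param sim the simulation the pipeline ran on.
#' @param enhancer_tol midpoint matching tolerance in bp (default 100).
#' @return list of recovery statistics (switch sensitivity and false
#'   calls, consequence accuracy, enhancer sensitivity/precision,
#'   transient-cluster purity, planted-motif top rank).
#' @export
compare_to_truth <- function(res, sim, enhancer_tol = 100L) {
  truth <- sim$truth
  assign <- res$consequence

  # promoter switches
  truth_sw <- truth$gene_id[truth$kind == "switch"]
  called_sw <- unique(res$switches$gene_id)
  kept_per_gene <- table(assign$gene_id[assign$kept])
  multi_tc <- names(kept_per_gene)[kept_per_gene >= 2L]
  false_sw <- setdiff(called_sw, truth_sw)
  switch_stats <- list(
    n_truth = length(truth_sw),
    n_called = length(called_sw),
    sensitivity = if (length(truth_sw))
      mean(truth_sw %in% called_sw) else NA_real_,
    false_calls = length(false_sw),
    n_unplanted_multi_tc = length(setdiff(multi_tc, truth_sw)))

  # consequence classes: the alternative TC of each planted gene must get
  # the planted class, and the primary TC must stay "none"
  cons_truth <- truth[truth$kind %in% c("uorf_skip", "domain_disrupt",
                                        "target_peptide"), , drop = FALSE]
  ok <- logical(nrow(cons_truth))
  for (i in seq_len(nrow(cons_truth))) {
    g <- cons_truth$gene_id[i]
    rows <- assign[!is.na(assign$gene_id) & assign$gene_id == g &
                     assign$kept, , drop = FALSE]
    if (nrow(rows) < 2L) next
    alt <- rows[which.min(abs(rows$peak - cons_truth$peak_alt[i])), ]
    pri <- rows[which.min(abs(rows$peak - cons_truth$peak_primary[i])), ]
    ok[i] <- identical(alt$consequence, cons_truth$class[i]) &&
      identical(pri$consequence, "none")
  }
  consequence_stats <- list(n_truth = nrow(cons_truth),
                            n_correct = sum(ok),
                            accuracy = if (nrow(cons_truth)) mean(ok)
                                       else NA_real_)

  # enhancers
  truth_mid <- truth$start[truth$kind == "enhancer"]
  called_mid <- if (length(res$enhancers)) res$enhancers$midpoint
                else integer(0)
  enh <- match_positions(called_mid, truth_mid, enhancer_tol)
  enhancer_stats <- list(n_truth = length(truth_mid),
                         n_called = length(called_mid),
                         sensitivity = enh$sens, precision = enh$prec)

  # transient-induced co-clustering and planted-motif enrichment
  cl <- res$deg_clusters$cluster
  transient_genes <- intersect(
    truth$gene_id[truth$kind == "deg_cluster" & truth$cluster == 5L],
    names(cl))
  transient_stats <- list(n_planted = length(transient_genes),
                          n_clustered = NA_integer_, purity = NA_real_,
                          label = NA_character_, one_cluster = NA)
  motif_stats <- list(planted_pwm = NA_character_,
                      top_pwm = NA_character_, top_rank_hit = NA)
  if (length(transient_genes)) {
    tab <- table(cl[transient_genes])
    main_cl <- names(tab)[which.max(tab)]
    transient_stats$n_clustered <- length(transient_genes)
    transient_stats$purity <- max(tab) / length(transient_genes)
    transient_stats$label <-
      unname(res$deg_clusters$label[as.integer(main_cl)])
    transient_stats$one_cluster <- length(tab) == 1L
    planted_pwm <- truth$id[truth$kind == "motif"]
    if (length(planted_pwm) && !is.null(res$tfbs) &&
        main_cl %in% rownames(res$tfbs$ratio)) {
      r <- res$tfbs$ratio[main_cl, ]
      motif_stats <- list(planted_pwm = planted_pwm[1],
                          top_pwm = names(r)[which.max(r)],
                          top_rank_hit =
                            names(r)[which.max(r)] == planted_pwm[1])
    }
  }
  list(switches = switch_stats, consequences = consequence_stats,
       enhancers = enhancer_stats, transient_cluster = transient_stats,
       motif = motif_stats)
}

#' Run the complete analysis pipeline on a simulated experiment
#'
#' Executes every stage with the study thresholds: CTSS support filter
#' (count >= 1 in >= 3 libraries), 20-bp neighbor clustering, TPM filter
#' (>= 1 TPM in >= 3 libraries), hierarchical annotation with a +/-100-bp
#' promoter window, 10%-in-3-libraries contribution gate, moderated DE at
#' |log2FC| >= 1 and FDR <= 0.05, DTU at |delta| >= 1 log2, six-cluster
#' trajectory clustering, 500-bp/0.95-balance enhancer scan with the
#' 3-sample bidirectionality filter, and 500-bp promoter PWM scanning at
#' 70% relative similarity.
#'
#' @param config a [simulation_config] (or a list of its arguments).
#' @param outdir optional directory for TSV/BED artifacts and the JSON
#'   summary.
#' @param g_offset_bp G-addition correction applied to the CTSS input
#'   (default 0: the simulator emits corrected coordinates).
#' @param params overrides for stage thresholds: a named list among
#'   `max_dist`, `min_tpm`, `min_libs`, `promoter_halfwidth`,
#'   `min_contribution`, `lfc_min`, `fdr_max`, `dtu_min_effect_log2`, `k`,
#'   `enh_window`, `enh_balance`, `enh_min_samples`, `pwm_min_similarity`,
#'   `promoter_width`.
#' @return list with all stage results (`ctss`, `tcset`, `assign`,
#'   `usage`, `de_gene`, `deg_clusters`, `de_tc`, `dtu`, `switches`,
#'   `consequence`, `enhancers`, `de_enh`, `promoters`, `tfbs`),
#'   `recovery` (truth comparison), `summary` (plain list) and
#'   `summary_json` (deterministic JSON string).
#' @export
run_pipeline <- function(config = simulation_config(), outdir = NULL,
                         g_offset_bp = 0L, params = list()) {
  p <- list(max_dist = 20L, min_tpm = 1, min_libs = 3L,
            promoter_halfwidth = 100L, min_contribution = 0.10,
            lfc_min = 1, fdr_max = 0.05, dtu_min_effect_log2 = 1,
            k = 6L, enh_window = 500L, enh_balance = 0.95,
            enh_min_samples = 3L, pwm_min_similarity = 0.70,
            promoter_width = 500L)
  bad <- setdiff(names(params), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(params)] <- params
  if (!is(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (p$min_libs > nrow(config$design))
    stop("min_libs exceeds the number of libraries in the design")

  sim <- simulate_experiment(config)
  ctss <- sim$ctss
  if (g_offset_bp > 0L) ctss <- apply_g_offset(ctss, g_offset_bp)
  ctss_f <- filter_ctss(ctss, min_count = 1L, min_libs = p$min_libs)
  tcs <- cluster_ctss(ctss_f, max_dist = p$max_dist)
  tcset <- quantify_tcs(tcs, ctss_f)
  tcset <- filter_tcs(tcset, min_tpm = p$min_tpm, min_libs = p$min_libs)

  assign <- assign_and_filter_intragenic(
    tcset, sim$ann, min_contribution = p$min_contribution,
    min_libs = p$min_libs, promoter_halfwidth = p$promoter_halfwidth)
  assign <- label_primary_major(assign, tcset, sim$ann,
                                promoter_halfwidth = p$promoter_halfwidth)
  usage <- usage_metrics(assign)

  gene_expr <- gene_expression(tcset, assign)
  de_gene <- fit_de(gene_expr$tpm, config$design,
                    lfc_min = p$lfc_min, fdr_max = p$fdr_max)
  deg_clusters <- call_and_cluster_degs(de_gene, gene_expr$tpm,
                                        config$design, k = p$k)

  kept <- assign$kept & !is.na(assign$gene_id)
  tc2gene <- setNames(assign$gene_id[kept], assign$tc_id[kept])
  tc_tpm <- tcset$tpm[match(names(tc2gene), tcset$gr$tc_id), ,
                      drop = FALSE]
  rownames(tc_tpm) <- names(tc2gene)
  de_tc <- fit_de(tc_tpm, config$design,
                  lfc_min = p$lfc_min, fdr_max = p$fdr_max)
  dtu <- dtu_test(de_tc, tc2gene,
                  min_effect_log2 = p$dtu_min_effect_log2,
                  fdr_max = p$fdr_max)
  categories <- setNames(assign$category, assign$tc_id)
  switches <- detect_switches(de_tc, tc2gene, categories,
                              lfc_min = p$lfc_min, fdr_max = p$fdr_max)

  consequence <- classify_consequences(assign, sim$ann)

  cands <- scan_bidirectional(ctss_f, window = p$enh_window,
                              balance_min = p$enh_balance,
                              seqlen = sim$ann$seqlen)
  enhancers <- filter_candidates(cands, sim$ann, ctss_f,
                                 min_samples = p$enh_min_samples)
  de_enh <- if (length(enhancers))
    de_enhancers(enhancers, ctss_f, lfc_min = p$lfc_min,
                 fdr_max = p$fdr_max)
  else NULL

  promoters <- define_promoters(sim$ann, assign,
                                width = p$promoter_width)
  tfbs <- NULL
  if (length(sim$pwms) && length(promoters)) {
    matches <- count_matches(promoters, sim$genome, sim$pwms,
                             min_similarity = p$pwm_min_similarity)
    tfbs <- enrichment_matrix(matches, deg_clusters$cluster)
    tfbs$matches <- matches
  }

  res <- list(sim = sim, ctss = ctss, tcset = tcset, assign = assign,
              usage = usage, gene_expr = gene_expr, de_gene = de_gene,
              deg_clusters = deg_clusters, de_tc = de_tc, dtu = dtu,
              switches = switches, consequence = consequence,
              enhancers = enhancers, de_enh = de_enh,
              promoters = promoters, tfbs = tfbs, params = p)
  res$recovery <- compare_to_truth(res, sim)

  n_per_gene <- table(assign$gene_id[assign$kept])
  deg_tab <- res$de_gene$table
  tnames <- time_contrast_names(de_gene$contrasts)
  summary <- list(
    seed = config$seed,
    n_libraries = nrow(config$design),
    total_tags = unname(sum(ctss$lib_sizes)),
    n_ctss = length(ctss$gr),
    n_ctss_filtered = length(ctss_f$gr),
    n_tcs = length(tcset$gr),
    n_genes_detected = length(n_per_gene),
    n_single_tc_genes = sum(n_per_gene == 1L),
    pct_single_tc_genes = unname(round(100 * mean(n_per_gene == 1L), 2)),
    tc_categories = as.list(table(assign$category[assign$kept])),
    degs_per_contrast = lapply(setNames(tnames, tnames), function(cn)
      sum(deg_tab$de[deg_tab$contrast == cn], na.rm = TRUE)),
    n_deg_clustered = length(deg_clusters$cluster),
    cluster_sizes = as.list(table(deg_clusters$cluster)),
    cluster_labels = as.list(setNames(deg_clusters$label,
                                      seq_along(deg_clusters$label))),
    n_dtu_tcs = length(dtu$dtu),
    n_switch_genes = length(unique(switches$gene_id)),
    consequence_classes =
      as.list(table(consequence$consequence[consequence$kept &
                                              !is.na(consequence$gene_id)])),
    n_enhancer_candidates = length(cands),
    n_enhancers_final = length(enhancers),
    enhancer_contexts = if (length(enhancers))
      as.list(table(enhancers$context)) else list(),
    recovery = res$recovery)
  res$summary <- summary
  res$summary_json <- jsonlite::toJSON(summary, auto_unbox = TRUE,
                                       digits = 10, pretty = TRUE)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(res$summary_json, file.path(outdir, "summary.json"))
    wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(consequence, "tc_annotation.tsv")
    wt(de_gene$table, "de_gene.tsv")
    wt(de_tc$table, "de_tc.tsv")
    if (nrow(dtu$table)) wt(dtu$table, "dtu.tsv")
    if (nrow(switches)) wt(switches, "switches.tsv")
    if (length(enhancers))
      wt(data.frame(chrom = as.character(seqnames(enhancers)),
                    start = start(enhancers) - 1L, end = end(enhancers),
                    name = enhancers$context,
                    score = floor(1000 * enhancers$balance),
                    strand = ".",
                    midpoint = enhancers$midpoint,
                    support = enhancers$support), "enhancers.bed")
    if (!is.null(tfbs)) {
      rt <- data.frame(cluster = rownames(tfbs$ratio), tfbs$ratio,
                       check.names = FALSE)
      wt(rt, "tfbs_enrichment.tsv")
    }
  }
  res
}
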