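# Moderated linear model, BH, trajectory clustering, DTU and switches.

# TPM matrix with log-normal noise around per-cell means (features x libs)
sim_tpm <- function(n_feat, design, lfc = NULL, base = 100, sdlog = 0.3,
                    seed = 1) {
  set.seed(seed)
  m <- matrix(base, n_feat, nrow(design))
  if (!is.null(lfc))
    for (j in seq_len(nrow(design)))
      m[, j] <- base * 2^(lfc(design[j, ]))
  m <- m * matrix(exp(rnorm(length(m), 0, sdlog)), n_feat)
  rownames(m) <- paste0("f", seq_len(n_feat))
  m
}

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(21)
  for (rep in 1:50) {
    p <- runif(sample(3:200, 1))
    expect_equal(p.adjust(p, "BH"), bf_bh(p), tolerance = 1e-14)
  }
})

test_that("a planted fold-change is estimated and called", {
  design <- mk_design(3, "wt", c(0, 30))
  lfc <- function(row) if (row$timepoint == 30) 3 else 0
  tpm <- rbind(sim_tpm(1, design, lfc, seed = 2),
               sim_tpm(199, design, seed = 3))
  fit <- fit_de(tpm, design)
  t30 <- fit$table[fit$table$contrast == "t30", ]
  expect_equal(t30$log2fc[1], 3, tolerance = 0.6)
  expect_true(t30$de[1])
  expect_lt(mean(t30$de[-1]), 0.02)     # null features stay quiet
})

test_that("planted log2FCs are recovered within 0.25 on average", {
  design <- mk_design(3, "wt", c(0, 30))
  planted <- rep(c(2, -2, 3, 1.5), 25)
  lfc_fun <- function(row) if (row$timepoint == 30) 1 else 0
  set.seed(31)
  m <- matrix(100, 100, nrow(design))
  for (j in seq_len(nrow(design)))
    if (design$timepoint[j] == 30) m[, j] <- 100 * 2^planted
  m <- m * matrix(exp(rnorm(length(m), 0, 0.3)), nrow(m))
  m <- rbind(m, sim_tpm(200, design, seed = 5))  # flat bulk for the norm
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  fit <- fit_de(m, design)
  est <- fit$table$log2fc[fit$table$contrast == "t30"][1:100]
  expect_lt(abs(mean(est - planted)), 0.25)   # unbiased on average
  expect_lt(mean(abs(est - planted)), 0.5)    # and individually close
})

test_that("planted gene-level effects are recovered on the default run", {
  res <- default_run_cached()
  truth <- res$sim$truth
  deg <- truth[truth$kind == "deg_cluster" & truth$cluster %in% c(1, 3), ]
  tab <- res$de_gene$table
  t30 <- tab[tab$contrast == "t30", ]
  est <- t30$log2fc[match(deg$gene_id, t30$feature_id)]
  planted <- ifelse(deg$cluster == 1, 1, -1) * deg$effect_log2
  expect_lt(abs(mean(est - planted)), 0.25)
})

test_that("the moderated fit agrees with the limma oracle", {
  skip_if_not_installed("limma")
  design <- mk_design(3, c("wt", "mut"), c(0, 30))
  tpm <- sim_tpm(150, design, seed = 4)
  fit <- fit_de(tpm, design, normalize = FALSE)
  y <- log2(tpm + 1)
  X <- stats::model.matrix(~ genotype * timepoint,
                           data = cagetc:::build_factors(design))
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_equal(unname(fit$coefficients), unname(t(lf$coefficients)),
               tolerance = 1e-10)
  expect_equal(unname(fit$s2), unname(lf$sigma^2), tolerance = 1e-10)
  expect_equal(fit$d0, lf$df.prior, tolerance = 0.05 * max(1, lf$df.prior))
  ours <- fit$table[fit$table$contrast == "t30", ]
  expect_equal(unname(ours$t), unname(lf$t[, "timepoint30"]),
               tolerance = 0.02)
})

test_that("aliased designs error and zero-variance features are flagged", {
  # genotype fully confounded with timepoint: wt at 0, mut at 30 only
  design <- mk_design(3, c("wt", "mut"), c(0, 30))
  design2 <- design[(design$genotype == "wt" & design$timepoint == 0) |
                      (design$genotype == "mut" & design$timepoint == 30), ]
  tpm <- sim_tpm(20, design2, seed = 6)
  expect_error(fit_de(tpm, design2), "aliased")
  d <- mk_design(3, "wt", c(0, 30))
  tpm2 <- sim_tpm(20, d, seed = 7)
  tpm2[1, ] <- 100                      # exactly constant feature
  fit <- fit_de(tpm2, d, normalize = FALSE)
  expect_true(is.na(fit$table$de[fit$table$feature_id == "f1"][1]))
  tpm3 <- matrix(100, 5, nrow(d), dimnames = list(paste0("f", 1:5), NULL))
  expect_error(fit_de(tpm3, d), "degenerate")
})

test_that("moderated t approaches the z limit when variances are pooled", {
  # identical residual variances force d0 -> Inf and s2_post -> s0^2
  design <- mk_design(3, "wt", c(0, 30))
  set.seed(8)
  noise <- rnorm(nrow(design))
  tpm <- 2^(matrix(10, 50, nrow(design)) +
              matrix(noise, 50, nrow(design), byrow = TRUE)) - 1
  rownames(tpm) <- paste0("f", 1:50)
  fit <- fit_de(tpm, design, normalize = FALSE)
  expect_true(is.infinite(fit$d0))
  expect_equal(unname(fit$s2_post), rep(fit$s2_post[[1]], 50))
})

test_that("identical trajectories co-cluster and shapes are labeled", {
  design <- mk_design(3, "wt", c(0, 10, 30))
  lfc <- function(row) {
    e <- c(`0` = 0, `10` = 3, `30` = 0)[as.character(row$timepoint)]
    unname(e)
  }
  tpm <- rbind(sim_tpm(10, design, lfc, sdlog = 0.1, seed = 9),
               sim_tpm(10, design,
                       function(row) if (row$timepoint == 30) -3 else 0,
                       sdlog = 0.1, seed = 10),
               sim_tpm(30, design, sdlog = 0.1, seed = 11))
  rownames(tpm) <- paste0("f", seq_len(nrow(tpm)))
  fit <- fit_de(tpm, design)
  cl <- call_and_cluster_degs(fit, tpm, design, k = 2)
  g1 <- cl$cluster[paste0("f", 1:10)]
  g2 <- cl$cluster[paste0("f", 11:20)]
  expect_equal(length(unique(g1)), 1L)
  expect_equal(length(unique(g2)), 1L)
  expect_false(unique(g1) == unique(g2))
  expect_equal(unname(cl$label[unique(g1)]), "induced_transient")
  expect_equal(unname(cl$label[unique(g2)]), "repressed_late")
  # constant features never enter the clustering
  expect_false(any(paste0("f", 21:50) %in% names(cl$cluster)))
})

mk_defit <- function(tab, contrasts = list(t30 = 1), df_total = 10) {
  structure(list(table = tab, contrasts = contrasts, df_total = df_total),
            class = "DEFit")
}

test_that("DTU deltas follow the closed form and ignore gene-level shifts", {
  design <- mk_design(3, "wt", c(0, 30))
  lfc <- function(row) 0
  set.seed(14)
  base <- sim_tpm(100, design, seed = 14)     # stable background
  a <- sim_tpm(1, design, function(r) if (r$timepoint == 30) 2 else 0,
               sdlog = 0.15, seed = 15)
  b <- sim_tpm(1, design, function(r) if (r$timepoint == 30) -2 else 0,
               sdlog = 0.15, seed = 16)
  tpm <- rbind(a, b, base)
  rownames(tpm) <- c("tcA", "tcB", paste0("f", seq_len(nrow(base))))
  fit <- fit_de(tpm, design)
  dtu <- dtu_test(fit, c(tcA = "g1", tcB = "g1"))
  dA <- dtu$table$delta_log2fc[dtu$table$tc_id == "tcA" &
                                 dtu$table$contrast == "t30"]
  expect_equal(dA, 4, tolerance = 0.8)
  expect_setequal(dtu$dtu, c("tcA", "tcB"))
  # adding a shared shift to a gene's TCs leaves deltas unchanged
  tab <- data.frame(feature_id = c("x", "y", "z"), contrast = "t30",
                    log2fc = c(1, 2, 6), se = 0.2, t = 1, p = 0.5,
                    fdr = 0.5, de = FALSE)
  f1 <- mk_defit(tab)
  tab2 <- tab; tab2$log2fc <- tab$log2fc + 5
  f2 <- mk_defit(tab2)
  g <- c(x = "g", y = "g", z = "g")
  expect_equal(dtu_test(f1, g)$table$delta_log2fc,
               dtu_test(f2, g)$table$delta_log2fc)
  # single-TC genes are skipped
  expect_equal(nrow(dtu_test(f1, c(x = "g1"))$table), 0L)
})

test_that("switch detection requires significant opposite directions", {
  tab <- data.frame(
    feature_id = c("up", "dn", "up2", "flat"),
    contrast = "t30",
    log2fc = c(2.5, -2, 1.5, 0.1), se = 0.2, t = 5,
    p = c(1e-5, 1e-4, 1e-3, 0.8),
    fdr = c(1e-4, 1e-3, 1e-2, 0.9),
    de = c(TRUE, TRUE, TRUE, FALSE))
  fit <- mk_defit(tab)
  sw <- detect_switches(fit, c(up = "g1", dn = "g1", up2 = "g2",
                               flat = "g2"),
                        categories = c(up = "promoter", dn = "CDS",
                                       up2 = "promoter", flat = "CDS"))
  expect_equal(sw$gene_id, "g1")
  expect_equal(sw$tc_up, "up")
  expect_equal(sw$tc_down, "dn")
  expect_equal(sw$category_down, "CDS")
  # both TCs up is not a switch
  tab$log2fc <- abs(tab$log2fc)
  expect_equal(nrow(detect_switches(mk_defit(tab),
                                    c(up = "g1", dn = "g1"))), 0L)
})
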