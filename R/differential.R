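# Moderated linear-model differential expression on log2 TPM over a
# genotype x timepoint factorial, empirical-Bayes variance shrinkage,
# trajectory clustering of responsive genes, differential TC usage and
# promoter-switch detection.

trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# moment-matching of log residual variances to a scaled F distribution:
# s2 ~ s0^2 * F(d, d0); returns prior df d0 (possibly Inf) and prior s0^2
fit_fdist <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) stop("all residual variances are zero; degenerate input")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  evar <- if (sum(ok) > 1) sd(e)^2 - trigamma(d / 2) else 0
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) - digamma(d0 / 2) + log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# modal location of a log-ratio distribution: kernel-density argmax,
# sharpened by iterated local means; robust to large asymmetric
# fractions of shifted values, unlike the median
modal_location <- function(x, halfwidth = 0.5) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(if (length(x)) x else 0)
  d <- stats::density(x)
  f0 <- d$x[which.max(d$y)]
  for (k in 1:3) {
    sel <- abs(x - f0) <= halfwidth
    if (any(sel)) f0 <- mean(x[sel])
  }
  f0
}

build_factors <- function(design) {
  geno_levels <- unique(design$genotype)
  if ("wt" %in% geno_levels)
    geno_levels <- c("wt", setdiff(geno_levels, "wt"))
  tp_levels <- sort(unique(design$timepoint))
  list(genotype = factor(design$genotype, levels = geno_levels),
       timepoint = factor(design$timepoint, levels = tp_levels))
}

#' Default contrasts for a genotype x timepoint design
#'
#' Time-course contrasts in the reference genotype (`t10`: 10 vs 0 min,
#' `t30`: 30 vs 0 min, `t3010`: 30 vs 10 min, for whatever timepoints are
#' present), one main-effect contrast per non-reference genotype, and the
#' genotype x timepoint interaction terms.
#'
#' @param X design matrix from [fit_de] (or `model.matrix`).
#' @return Named list of numeric contrast vectors over `colnames(X)`.
#' @export
default_contrasts <- function(X) {
  cn <- colnames(X)
  unit <- function(col) {
    v <- setNames(numeric(length(cn)), cn)
    v[col] <- 1
    v
  }
  out <- list()
  tp_cols <- grep("^timepoint", cn, value = TRUE)
  for (col in tp_cols)
    out[[paste0("t", sub("^timepoint", "", col))]] <- unit(col)
  if (all(c("timepoint10", "timepoint30") %in% cn))
    out[["t3010"]] <- unit("timepoint30") - unit("timepoint10")
  geno_cols <- grep("^genotype[^:]*$", cn, value = TRUE)
  for (col in geno_cols)
    out[[sub("^genotype", "genotype_", col)]] <- unit(col)
  int_cols <- grep(":", cn, value = TRUE, fixed = TRUE)
  for (col in int_cols)
    out[[gsub("genotype|timepoint", "",
              sub(":", "_x_t", col, fixed = TRUE))]] <- unit(col)
  out
}

time_contrast_names <- function(contrasts)
  grep("^t[0-9]+$", names(contrasts), value = TRUE)

#' Moderated differential expression over a genotype x timepoint design
#'
#' Fits, per feature, ordinary least squares of `log2(TPM + pseudo)` on the
#' full-factorial design `~ genotype * timepoint`. Residual variances are
#' shrunk by empirical Bayes towards a common prior:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, with the prior `(d0, s0^2)`
#' estimated by moment-matching the observed log-variance distribution to a
#' scaled F distribution. Moderated t statistics use `d0 + d` degrees of
#' freedom; p-values are BH-adjusted within each contrast.
#'
#' Cells absent from the design (e.g. a genotype sampled at fewer
#' timepoints) alias their interaction columns; identically-zero columns
#' are dropped before fitting, and any remaining rank deficiency is an
#' error naming the aliased terms.
#'
#' @param tpm numeric matrix, features x libraries (TPM scale).
#' @param design sample design data.frame (rows match columns of `tpm`).
#' @param contrasts named list of contrast vectors; defaults to
#'   [default_contrasts] of the design matrix.
#' @param pseudo pseudo-count added before log2 (default 1 TPM).
#' @param normalize align each design cell on the modal per-feature log2
#'   ratio to the baseline cell (reference genotype at the earliest
#'   timepoint) before fitting (default `TRUE`). This plays the role of
#'   between-sample normalization factors in count-based pipelines: under
#'   fixed sequencing depth, strongly induced transcripts crowd out
#'   unchanged ones and shift the whole TPM scale; anchoring on the
#'   densest mass of unchanged features removes that shift even when the
#'   responding fraction is large and one-sided (where a median would be
#'   dragged into the responding mass).
#' @param lfc_min,fdr_max thresholds for the `de` call (defaults 1, 0.05).
#' @return An object of class `DEFit`: list with `table` (long data.frame:
#'   `feature_id`, `contrast`, `log2fc`, `se`, `t`, `p`, `fdr`, `de`),
#'   `coefficients`, `s2`, `s2_post`, `d0`, `d`, `df_total`, `X`,
#'   `contrasts`, `zero_variance` (flagged feature ids).
#' @export
fit_de <- function(tpm, design, contrasts = NULL, pseudo = 1,
                   normalize = TRUE, lfc_min = 1, fdr_max = 0.05) {
  stopifnot(ncol(tpm) == nrow(design))
  if (is.null(rownames(tpm)))
    rownames(tpm) <- paste0("feature_", seq_len(nrow(tpm)))
  fac <- build_factors(design)
  terms <- c("genotype", "timepoint")[c(nlevels(fac$genotype) > 1L,
                                        nlevels(fac$timepoint) > 1L)]
  if (!length(terms))
    stop("design has a single genotype and a single timepoint")
  X <- model.matrix(stats::as.formula(paste("~", paste(terms,
                                                       collapse = " * "))),
                    data = fac)
  empty <- colSums(abs(X)) == 0
  if (any(empty)) X <- X[, !empty, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is confounded; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X); d <- n - p
  if (d < 1) stop("no residual degrees of freedom (need replicates)")
  y <- t(log2(tpm + pseudo))                      # n x features
  if (normalize && nrow(tpm) > 1L) {
    base_libs <- which(fac$genotype == levels(fac$genotype)[1] &
                         fac$timepoint == levels(fac$timepoint)[1])
    if (!length(base_libs)) base_libs <- seq_len(nrow(y))
    ref <- colMeans(y[base_libs, , drop = FALSE])
    cells <- interaction(fac$genotype, fac$timepoint, drop = TRUE)
    sizef <- numeric(nrow(y))
    for (cl in levels(cells)) {
      libs <- which(cells == cl)
      sizef[libs] <- modal_location(
        colMeans(y[libs, , drop = FALSE]) - ref)
    }
    y <- sweep(y, 1, sizef)
  }
  beta <- qr.coef(qrX, y)                         # p x features
  res <- y - X %*% beta
  s2 <- colSums(res^2) / d
  zv <- s2 <= .Machine$double.eps * 100
  zero_var <- rownames(tpm)[zv]
  if (all(zv))
    stop("all residual variances are zero; degenerate input")
  pri <- fit_fdist(s2[!zv], d)
  d0 <- pri$d0
  s2_post <- if (is.finite(d0)) (d0 * pri$s0_2 + d * s2) / (d0 + d)
             else rep(pri$s0_2, length(s2))
  df_total <- d0 + d
  if (is.null(contrasts)) contrasts <- default_contrasts(X)
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  tabs <- lapply(names(contrasts), function(cname) {
    cv <- contrasts[[cname]]
    stopifnot(length(cv) == p)
    lfc <- as.numeric(crossprod(cv, beta))
    unscaled <- as.numeric(t(cv) %*% XtXinv %*% cv)
    se <- sqrt(s2_post * unscaled)
    tt <- lfc / se
    pp <- 2 * pt(-abs(tt), df = df_total)
    fdr <- p.adjust(pp, method = "BH")
    data.frame(feature_id = rownames(tpm), contrast = cname,
               log2fc = lfc, se = se, t = tt, p = pp, fdr = fdr,
               de = abs(lfc) >= lfc_min & fdr <= fdr_max,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  table <- do.call(rbind, tabs)
  table$de[table$feature_id %in% zero_var] <- NA
  norm_log2 <- t(y)
  dimnames(norm_log2) <- list(rownames(tpm), design$library_id)
  structure(list(table = table, norm_log2 = norm_log2,
                 coefficients = beta, s2 = s2,
                 s2_post = s2_post, d0 = d0, d = d, df_total = df_total,
                 X = X, contrasts = contrasts, zero_variance = zero_var,
                 lfc_min = lfc_min, fdr_max = fdr_max),
            class = "DEFit")
}

#' @export
print.DEFit <- function(x, ...) {
  cat("DEFit:", length(x$s2), "features,", length(x$contrasts),
      "contrasts; prior df d0 =", signif(x$d0, 4), "\n")
  invisible(x)
}

#' Cluster responsive genes by expression trajectory
#'
#' Selects features called differentially expressed in any time-course
#' contrast, z-scores their mean normalized log2 expression (as fitted by
#' [fit_de]) over the reference-genotype timepoints, and clusters the
#' trajectories by hierarchical clustering
#' with complete linkage on correlation distance (1 - Pearson r), cutting
#' the tree at `k` clusters. Each cluster is labeled induced/repressed and
#' early-sustained/late/transient from its mean trajectory.
#'
#' @param defit a `DEFit` at gene level.
#' @param tpm the gene-level TPM matrix used for the fit (fallback when
#'   the fit carries no normalized matrix).
#' @param design sample design.
#' @param k number of clusters (default 6); reduced with a warning when
#'   fewer responsive genes exist.
#' @param genotype reference genotype whose trajectory is clustered
#'   (default `"wt"`).
#' @return list with `cluster` (named integer vector), `label` (cluster ->
#'   shape label), `z` (gene x timepoint z-score matrix), `timepoints`.
#' @export
call_and_cluster_degs <- function(defit, tpm, design, k = 6L,
                                  genotype = "wt") {
  tnames <- time_contrast_names(defit$contrasts)
  tab <- defit$table
  degs <- unique(tab$feature_id[tab$contrast %in% tnames &
                                  tab$de %in% TRUE])
  if (length(degs) < 2L) stop("fewer than 2 responsive features to cluster")
  if (length(degs) < k) {
    warning("only ", length(degs), " responsive features; k reduced")
    k <- length(degs)
  }
  expr <- if (!is.null(defit$norm_log2)) defit$norm_log2
          else log2(tpm + 1)
  if (is.null(colnames(expr))) colnames(expr) <- design$library_id
  tps <- sort(unique(design$timepoint[design$genotype == genotype]))
  m <- sapply(tps, function(tp) {
    libs <- design$library_id[design$genotype == genotype &
                                design$timepoint == tp]
    rowMeans(expr[degs, libs, drop = FALSE])
  })
  colnames(m) <- paste0("t", tps)
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0
  dst <- as.dist(1 - cor(t(z)))
  hc <- hclust(dst, method = "complete")
  cl <- cutree(hc, k = k)
  label <- vapply(seq_len(k), function(ci) {
    mt <- colMeans(z[cl == ci, , drop = FALSE])
    dev <- mt - mt[1]
    peak <- which.max(abs(dev[-1])) + 1L
    dir <- if (dev[peak] > 0) "induced" else "repressed"
    d10 <- dev[2]; dend <- dev[length(dev)]
    shape <- if (abs(d10) >= abs(dend) * 2) "transient"
             else if (abs(d10) <= abs(dend) / 2) "late"
             else "early_sustained"
    paste(dir, shape, sep = "_")
  }, character(1))
  list(cluster = cl, label = label, z = z, timepoints = tps)
}

#' Differential TC usage (diffSplice-style delta test)
#'
#' For every gene with at least two retained TCs and every contrast, tests
#' whether a TC's log2 fold-change departs from the average log2
#' fold-change of the gene's other TCs: `delta = lfc_TC - mean(lfc_others)`,
#' with a moderated t test (variance from the TCs' moderated standard
#' errors), BH-corrected within contrast. A TC is reported as DTU iff it
#' reaches `fdr <= fdr_max` with `|delta| >= min_effect_log2` in at least
#' one time-course contrast.
#'
#' @param defit a TC-level `DEFit`.
#' @param tc2gene named character vector, TC id -> gene id (only retained
#'   intragenic TCs).
#' @param min_effect_log2 minimal |delta| in log2 units (default 1,
#'   i.e. a linear fold-change of 2).
#' @param fdr_max BH threshold (default 0.05).
#' @return list with `table` (tc_id, gene_id, contrast, delta_log2fc, t,
#'   p, fdr) and `dtu` (character vector of DTU TC ids).
#' @export
dtu_test <- function(defit, tc2gene, min_effect_log2 = 1, fdr_max = 0.05) {
  genes <- split(names(tc2gene), tc2gene)
  genes <- genes[lengths(genes) >= 2L]
  tnames <- time_contrast_names(defit$contrasts)
  rows <- list()
  for (cname in tnames) {
    sub <- defit$table[defit$table$contrast == cname, ]
    lfc <- setNames(sub$log2fc, sub$feature_id)
    se <- setNames(sub$se, sub$feature_id)
    for (g in names(genes)) {
      tcs <- genes[[g]]
      if (!all(tcs %in% names(lfc))) next
      m <- length(tcs)
      for (tc in tcs) {
        others <- setdiff(tcs, tc)
        delta <- lfc[tc] - mean(lfc[others])
        vdelta <- se[tc]^2 + sum(se[others]^2) / (m - 1)^2
        tt <- delta / sqrt(vdelta)
        rows[[length(rows) + 1L]] <-
          data.frame(tc_id = tc, gene_id = g, contrast = cname,
                     delta_log2fc = unname(delta), t = unname(tt),
                     p = 2 * pt(-abs(tt), df = defit$df_total),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(list(table = data.frame(), dtu = character(0)))
  tab <- do.call(rbind, rows)
  tab$fdr <- NA_real_
  for (cname in unique(tab$contrast)) {
    i <- tab$contrast == cname
    tab$fdr[i] <- p.adjust(tab$p[i], method = "BH")
  }
  hit <- tab$fdr <= fdr_max & abs(tab$delta_log2fc) >= min_effect_log2
  list(table = tab, dtu = unique(tab$tc_id[hit]))
}

#' Detect promoter (TSS) switches
#'
#' A gene is flagged as a switch gene when, in the same contrast, one of
#' its TCs is significantly up- (`log2fc >= lfc_min`, `fdr <= fdr_max`) and
#' another significantly downregulated (`log2fc <= -lfc_min`). The most
#' extreme up/down pair per gene and contrast is reported together with the
#' TCs' annotation categories.
#'
#' @param defit a TC-level `DEFit`.
#' @param tc2gene named character vector, TC id -> gene id.
#' @param categories optional named vector, TC id -> annotation category.
#' @param lfc_min,fdr_max significance thresholds (defaults 1, 0.05).
#' @param contrasts contrast names to scan; defaults to the time-course
#'   contrasts.
#' @return data.frame: `gene_id`, `contrast`, `tc_up`, `tc_down`,
#'   `log2fc_up`, `log2fc_down`, `category_up`, `category_down`.
#' @export
detect_switches <- function(defit, tc2gene, categories = NULL,
                            lfc_min = 1, fdr_max = 0.05,
                            contrasts = NULL) {
  if (is.null(contrasts))
    contrasts <- time_contrast_names(defit$contrasts)
  genes <- split(names(tc2gene), tc2gene)
  genes <- genes[lengths(genes) >= 2L]
  rows <- list()
  for (cname in contrasts) {
    sub <- defit$table[defit$table$contrast == cname, ]
    sig_up <- sub$feature_id[sub$log2fc >= lfc_min &
                               sub$fdr <= fdr_max & !is.na(sub$fdr)]
    sig_dn <- sub$feature_id[sub$log2fc <= -lfc_min &
                               sub$fdr <= fdr_max & !is.na(sub$fdr)]
    lfc <- setNames(sub$log2fc, sub$feature_id)
    for (g in names(genes)) {
      ups <- intersect(genes[[g]], sig_up)
      dns <- intersect(genes[[g]], sig_dn)
      if (!length(ups) || !length(dns)) next
      up <- ups[which.max(lfc[ups])]
      dn <- dns[which.min(lfc[dns])]
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, contrast = cname, tc_up = up, tc_down = dn,
                   log2fc_up = unname(lfc[up]),
                   log2fc_down = unname(lfc[dn]),
                   category_up = if (is.null(categories)) NA_character_
                                 else unname(categories[up]),
                   category_down = if (is.null(categories)) NA_character_
                                   else unname(categories[dn]),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), contrast = character(0),
                      tc_up = character(0), tc_down = character(0),
                      log2fc_up = numeric(0), log2fc_down = numeric(0),
                      category_up = character(0),
                      category_down = character(0)))
  do.call(rbind, rows)
}
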