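# Hierarchical TC annotation, contribution gate, labels and diversity.

# TagClusterSet with given peaks/strands and a TPM matrix (lib sizes 1e6)
mk_tcset <- function(peaks, strands, tpm, chrom = "chr1") {
  tpm <- as.matrix(tpm)
  design <- mk_design(ncol(tpm))
  gr <- GRanges(chrom, IRanges(peaks, width = 1L), strand = strands)
  gr$tc_id <- paste0("tc", seq_along(gr))
  gr$peak <- peaks
  structure(list(gr = gr, counts = tpm, tpm = tpm,
                 lib_sizes = setNames(rep(1e6, ncol(tpm)),
                                      design$library_id),
                 design = design),
            class = "TagClusterSet")
}

test_that("peak category follows the promoter-first hierarchy", {
  ann <- toy_annotation()
  # GP (+): TSS 2001, CDS from 2211, intron 2451..3150; GM (-): TSS 14191
  tcs <- mk_tcset(
    peaks = c(1961L, 2700L, 2300L, 13000L, 9000L, 4100L),
    strands = c("+", "+", "+", "+", "-", "+"),
    tpm = matrix(10, 6, 3))
  cat <- as.character(annotate_tcs(tcs, ann))
  expect_equal(cat[1], "promoter")    # 40 bp upstream of the TSS
  expect_equal(cat[2], "intron")
  expect_equal(cat[3], "CDS")
  expect_equal(cat[4], "antisense")   # plus-strand TC inside minus gene
  expect_equal(cat[5], "intergenic")
  expect_equal(cat[6], "threeUTR")    # past the stop codon at 4041
})

test_that("leader TCs are fiveUTR and the minus-strand gene mirrors", {
  ann <- toy_annotation()
  tcs <- mk_tcset(peaks = c(2150L, 14050L, 12300L),
                  strands = c("+", "-", "-"),
                  tpm = matrix(10, 3, 3))
  cat <- as.character(annotate_tcs(tcs, ann))
  expect_equal(cat, c("fiveUTR", "fiveUTR", "CDS"))
})

test_that("contribution gate keeps TCs at or above 10% in 3 libraries", {
  ann <- toy_annotation()
  tcs <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                  tpm = rbind(c(90, 90, 90), c(10, 10, 10)))
  a <- assign_and_filter_intragenic(tcs, ann)
  expect_equal(a$gene_id, c("GP", "GP"))
  expect_true(all(a$kept))            # 10% boundary is inclusive
  tcs2 <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                   tpm = rbind(c(95, 95, 95), c(5, 5, 5)))
  a2 <- assign_and_filter_intragenic(tcs2, ann)
  expect_equal(a2$kept, c(TRUE, FALSE))
})

test_that("per-library gating matches a brute-force fraction check", {
  set.seed(12)
  ann <- toy_annotation()
  for (rep in 1:20) {
    tpm <- matrix(rexp(4 * 6, 1 / 20), 4, 6)
    tcs <- mk_tcset(peaks = c(2001L, 2300L, 2700L, 3900L), strands = "+",
                    tpm = tpm)
    a <- assign_and_filter_intragenic(tcs, ann, min_contribution = 0.10,
                                      min_libs = 3)
    frac <- sweep(tpm, 2, colSums(tpm), "/")
    expect_equal(a$kept, rowSums(frac >= 0.10) >= 3)
  }
})

test_that("primary/major labels follow the annotated TSS and expression", {
  ann <- toy_annotation()
  one <- mk_tcset(peaks = 2001L, strands = "+", tpm = matrix(50, 1, 3))
  a1 <- label_primary_major(assign_and_filter_intragenic(one, ann),
                            one, ann)
  expect_true(a1$is_primary & a1$is_major)
  two <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                  tpm = rbind(c(20, 20, 20), c(60, 60, 60)))
  a2 <- label_primary_major(assign_and_filter_intragenic(two, ann),
                            two, ann)
  expect_equal(a2$is_primary, c(TRUE, FALSE))
  expect_equal(a2$is_major, c(FALSE, TRUE))   # downstream TC dominates
  tie <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                  tpm = rbind(c(50, 50, 50), c(50, 50, 50)))
  a3 <- label_primary_major(assign_and_filter_intragenic(tie, ann),
                            tie, ann)
  expect_equal(a3$is_major, c(TRUE, FALSE))   # 5'-most wins ties
})

test_that("major labels equal an argmax oracle on random gene profiles", {
  set.seed(13)
  ann <- toy_annotation()
  for (rep in 1:25) {
    tpm <- matrix(rexp(3 * 5, 1 / 30) + 20, 3, 5)
    tcs <- mk_tcset(peaks = c(2001L, 2300L, 2700L), strands = "+",
                    tpm = tpm)
    a <- label_primary_major(assign_and_filter_intragenic(tcs, ann),
                             tcs, ann)
    expect_equal(which(a$is_major), which.max(rowMeans(tpm)))
  }
})

test_that("Simpson diversity takes its closed-form values", {
  ann <- toy_annotation()
  one <- mk_tcset(peaks = 2001L, strands = "+", tpm = matrix(50, 1, 3))
  u1 <- usage_metrics(assign_and_filter_intragenic(one, ann))
  expect_equal(u1$gene$simpson, 0)
  even <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                   tpm = rbind(c(50, 50, 50), c(50, 50, 50)))
  u2 <- usage_metrics(assign_and_filter_intragenic(even, ann))
  expect_equal(u2$gene$simpson, 0.5, tolerance = 1e-12)
  skew <- mk_tcset(peaks = c(2001L, 2700L), strands = "+",
                   tpm = rbind(c(90, 90, 90), c(10, 10, 10)))
  u3 <- usage_metrics(assign_and_filter_intragenic(skew, ann))
  expect_equal(u3$gene$simpson, 0.18, tolerance = 1e-12)
  # same convention as the vegan diversity routine
  expect_equal(u3$gene$simpson,
               unname(vegan::diversity(c(0.9, 0.1), "simpson")))
})

test_that("ranks order by contribution and usage sums to one", {
  ann <- toy_annotation()
  tcs <- mk_tcset(peaks = c(2001L, 2300L, 2700L), strands = "+",
                  tpm = rbind(c(20, 20, 20), c(70, 70, 70), c(10, 10, 10)))
  u <- usage_metrics(assign_and_filter_intragenic(tcs, ann))
  expect_equal(u$tc$rank, c(2L, 1L, 3L))
  expect_equal(sum(u$tc$fractional_usage), 1, tolerance = 1e-9)
})

test_that("dominant-TC usage rises with expression on the default run", {
  res <- default_run_cached()
  u <- res$usage
  multi <- u$gene$gene_id[u$gene$n_tc >= 2]
  r1 <- u$tc[u$tc$rank %in% 1L & u$tc$gene_id %in% multi, ]
  expr <- rowMeans(res$gene_expr$tpm)[r1$gene_id]
  rho <- suppressWarnings(
    stats::cor(expr, r1$fractional_usage, method = "spearman"))
  expect_gt(rho, 0)
})
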