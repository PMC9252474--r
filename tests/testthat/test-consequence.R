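# Consequence classification: domains, target peptides, uORFs.

mk_assign <- function(peaks, gene_id, strand, category = "CDS",
                      tc_id = NULL) {
  data.frame(tc_id = if (is.null(tc_id)) paste0("tc", seq_along(peaks))
             else tc_id,
             chrom = "chr1", peak = peaks, strand = strand,
             category = category, gene_id = gene_id,
             contribution = 1, kept = TRUE, stringsAsFactors = FALSE)
}

test_that("domain amino-acid spans map to genomic segments", {
  # single-exon CDS starting at 2001 (+): aa 1-10 -> first 30 nt
  ann <- GenomeAnnotation(
    GRanges("chr1", IRanges(2001, 2900), strand = "+", gene_id = "g1"),
    data.frame(transcript_id = "t1", gene_id = "g1"),
    GRangesList(t1 = GRanges("chr1", IRanges(2001, 2900), strand = "+")),
    GRangesList(t1 = GRanges("chr1", IRanges(2001, 2900), strand = "+")),
    domains = data.frame(transcript_id = "t1", aa_start = 1L,
                         aa_end = 10L, label = "D"),
    seqlen = c(chr1 = 10000L))
  segs <- domains_to_genome(ann)[[1]]
  expect_equal(start(segs), 2001L)
  expect_equal(end(segs), 2030L)
  expect_error(domains_to_genome(
    ann, data.frame(transcript_id = "t1", aa_start = 1L, aa_end = 400L,
                    label = "D")), "protein length")
})

test_that("intron-spanning domains keep 3x the amino-acid span", {
  ann <- toy_annotation()
  doms <- data.frame(transcript_id = c("GP.1", "GM.1"),
                     aa_start = 40L, aa_end = 200L, label = "DOM")
  segs <- domains_to_genome(ann, doms)
  for (i in 1:2) {
    expect_gt(length(segs[[i]]), 1L)          # crosses an intron
    expect_equal(sum(width(segs[[i]])), 3L * (200L - 40L + 1L))
  }
  # per-base codon walk oracle: segments equal the walked CDS positions
  for (tx in c("GP.1", "GM.1")) {
    walk <- bf_spliced_positions(ann$cds_by_tx[[tx]])
    expected <- sort(walk[(3 * 39 + 1):(3 * 200)])
    seg <- segs[[which(doms$transcript_id == tx)]]
    expect_equal(sort(unlist(lapply(seq_along(seg), function(i)
      start(seg)[i]:end(seg)[i]))), expected)
  }
})

test_that("domain disruption means peak within or downstream, sense only", {
  ann <- toy_annotation()
  ann$domains <- data.frame(transcript_id = c("GP.1", "GM.1"),
                            aa_start = 40L, aa_end = 200L, label = "DOM")
  # GP (+): domain starts at CDS nt 118 -> genomic 2001+210+117 = 2328
  a <- mk_assign(peaks = c(2327L, 2328L, 3200L, 2005L),
                 gene_id = "GP", strand = "+",
                 category = c("CDS", "CDS", "CDS", "promoter"))
  f <- classify_domain_disruption(a, ann)
  expect_equal(f, c(FALSE, TRUE, TRUE, FALSE))
  # GM (-): domain 5' start mirrors at 13981-117 = 13864
  am <- mk_assign(peaks = c(13865L, 13864L, 12600L), gene_id = "GM",
                  strand = "-")
  expect_equal(classify_domain_disruption(am, ann),
               c(FALSE, TRUE, TRUE))
  anti <- mk_assign(10000L, NA_character_, "+", category = "antisense")
  expect_true(is.na(classify_domain_disruption(anti, ann)))
})

test_that("target peptide exclusion uses the 3x cleavage-site span", {
  ann <- toy_annotation()
  ann$target_peptides <- data.frame(transcript_id = "GP.1",
                                    cleavage_aa = 60L, kind = "plastid")
  # peptide = first 180 coding nt; 5' genomic start = 2211
  a <- mk_assign(peaks = c(2210L, 2211L, 3200L), gene_id = "GP",
                 strand = "+", category = c("fiveUTR", "CDS", "CDS"))
  expect_equal(classify_target_peptide(a, ann), c(FALSE, TRUE, TRUE))
  # genes without a record are not evaluated
  am <- mk_assign(13000L, "GM", "-")
  expect_true(is.na(classify_target_peptide(am, ann)))
})

test_that("uORF scanning finds ATG...stop ORFs in the leader", {
  u <- scan_uorfs("AAATGGCCTAACC")
  expect_equal(nrow(u), 1L)
  expect_equal(u$tx_start, 3L)
  expect_equal(u$tx_end, 11L)
  expect_equal(u$length_nt, 9L)
  expect_equal(nrow(scan_uorfs("CCCCCCGGGTTT")), 0L)   # no ATG
  expect_equal(nrow(scan_uorfs("ATGAA")), 0L)          # shorter than 6
  # ATG without an in-frame stop in the leader is not a uORF
  expect_equal(nrow(scan_uorfs("AAATGGGGGGGG")), 0L)
})

test_that("uORF scanner equals a three-frame brute-force oracle", {
  set.seed(23)
  bf_uorfs <- function(s, min_len = 6) {
    out <- data.frame(tx_start = integer(0), tx_end = integer(0))
    n <- nchar(s)
    for (i in seq_len(max(n - 5, 0))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        if (substr(s, j, j + 2) %in% c("TAA", "TAG", "TGA")) {
          if (j + 2 - i + 1 >= min_len)
            out <- rbind(out, data.frame(tx_start = i, tx_end = j + 2))
          break
        }
        j <- j + 3
      }
    }
    out
  }
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:200, 1),
                      replace = TRUE), collapse = "")
    got <- scan_uorfs(s)
    exp <- bf_uorfs(s)
    expect_equal(got[c("tx_start", "tx_end")],
                 exp[order(exp$tx_start, exp$tx_end), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("uORF skipping uses strict within-or-downstream peak logic", {
  ann <- toy_annotation()
  # two uORFs in GP's leader (tx coords; leader is tx 1..210)
  ann$uorfs <- data.frame(transcript_id = c("GP.1", "GP.1"),
                          tx_start = c(31L, 121L), tx_end = c(60L, 150L))
  # genomic starts: 2001+30 = 2031 and 2001+120 = 2121
  a <- mk_assign(peaks = c(2030L, 2031L, 2100L, 2180L), gene_id = "GP",
                 strand = "+", category = "fiveUTR")
  res <- classify_uorf_content(a, ann)
  expect_equal(res$skips_any, c(FALSE, TRUE, TRUE, TRUE))
  per <- res$per_uorf
  # intermediate TC at 2100 skips the first uORF but retains the second
  mid <- per[per$tc_id == "tc3", ]
  expect_equal(mid$skipped[mid$uorf == 1], TRUE)
  expect_equal(mid$skipped[mid$uorf == 2], FALSE)
  # minus-strand gene: uORF at tx 31..60 starts at 14191-30 = 14161
  ann$uorfs <- data.frame(transcript_id = "GM.1", tx_start = 31L,
                          tx_end = 60L)
  am <- mk_assign(peaks = c(14162L, 14161L, 14000L), gene_id = "GM",
                  strand = "-", category = "fiveUTR")
  expect_equal(classify_uorf_content(am, ann)$skips_any,
               c(FALSE, TRUE, TRUE))
})

test_that("consequence classes are assigned with documented precedence", {
  ann <- toy_annotation()
  ann$domains <- data.frame(transcript_id = "GP.1", aa_start = 40L,
                            aa_end = 200L, label = "DOM")
  ann$uorfs <- data.frame(transcript_id = "GP.1", tx_start = 31L,
                          tx_end = 60L)
  a <- mk_assign(peaks = c(2005L, 2100L, 3200L), gene_id = "GP",
                 strand = "+",
                 category = c("promoter", "fiveUTR", "CDS"))
  cc <- classify_consequences(a, ann)
  expect_equal(cc$consequence,
               c("none", "uorf_skipping", "domain_disruptive"))
})
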