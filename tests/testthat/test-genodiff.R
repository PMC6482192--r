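test_that("genetic models collapse genotype triples as defined", {
  a <- c(6L, 3L, 1L)  # (homref, het, homalt)
  b <- c(2L, 4L, 4L)
  expect_equal(unname(model_table(a, b, "dominant")[1L, ]), c(4L, 6L))
  expect_equal(unname(model_table(a, b, "allelic")[1L, ]), c(5L, 15L))
  expect_equal(unname(model_table(c(0L, 0L, 10L), b, "recessive")[1L, ]),
               c(10L, 0L))
  expect_equal(unname(model_table(a, b, "codominant")[2L, ]), b)
  expect_equal(dim(model_table(a, b, "trend")), c(2L, 3L))
  # cell totals conserved (alleles for the allelic model)
  expect_equal(sum(model_table(a, b, "dominant")), 20L)
  expect_equal(sum(model_table(a, b, "allelic")), 40L)
  expect_error(model_table(a, b, "additive"), "arg")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))), 2 / 184756,
               tolerance = 1e-12)
  set.seed(14)
  for (rep in 1:60) {
    tab <- matrix(sample(0:10, 4L, replace = TRUE), 2L)
    if (sum(tab) == 0L) next
    expect_equal(fisher_exact_2x2(tab), brute_fisher(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(1, 2L, 3L)), "2x2")
})

test_that("codominant chi-square drops empty classes and reduces df", {
  expect_equal(chisq_2x3(rbind(c(4, 3, 3), c(4, 3, 3))), 1)
  # empty middle class: df 1, statistic 20
  p <- chisq_2x3(rbind(c(10, 0, 0), c(0, 0, 10)))
  expect_equal(p, pchisq(20, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  # Pearson formula oracle on random tables with all classes present
  set.seed(24)
  for (rep in 1:20) {
    tab <- matrix(sample(1:10, 6L, replace = TRUE), 2L)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - expected)^2 / expected)
    expect_equal(chisq_2x3(tab),
                 pchisq(stat, df = 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chisq_2x3(rbind(c(0, 0, 0), c(1, 2, 3))), "zero samples")
})

test_that("the trend test matches the closed-form statistic", {
  expect_equal(suppressWarnings(
    cochran_armitage(rbind(c(4, 3, 3), c(4, 3, 3)))), 1)
  # maximal trend [[10,0,0],[0,0,10]]: hand-computed statistic = 20
  p <- cochran_armitage(rbind(c(10, 0, 0), c(0, 0, 10)))
  expect_equal(p, pchisq(20, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  # affine invariance of the dose vector
  tab <- rbind(c(5, 3, 2), c(1, 4, 5))
  expect_equal(cochran_armitage(tab, c(0, 1, 2)),
               cochran_armitage(tab, c(0, 2, 4)))
  expect_equal(cochran_armitage(tab, c(0, 1, 2)),
               cochran_armitage(tab, c(3, 5, 7)))
  expect_warning(p0 <- cochran_armitage(rbind(c(5, 0, 0), c(5, 0, 0))),
                 "zero trend")
  expect_equal(p0, 1)
})

test_that("identical genotype distributions are never flagged", {
  hap <- random_hap(8L, 10L)
  hap <- rbind(hap, hap)  # farm samples identical to wild
  ds <- toy_ds(hap, seq(1000L, by = 1000L, length.out = 10L),
               rep(c("wild", "farm"), each = 4L))
  gd <- suppressMessages(
    scan_differentiated_loci(ds, "farm", "wild"))
  expect_true(all(gd$p_min > 1 - 1e-9))
  expect_false(any(gd$differentiating))
})

test_that("a fixed difference inside a gene is flagged under every model", {
  hap <- rbind(matrix(0L, 20L, 1L), matrix(1L, 20L, 1L))
  ds <- toy_ds(hap, 5000L, rep(c("wild", "farm"), each = 10L))
  genes <- data.frame(id = "g1", chrom = "chr1", start = 4000L,
                      end = 6000L, strand = "+", coverage = NA_real_)
  gd <- scan_differentiated_loci(ds, "farm", "wild", genes = genes)
  expect_equal(nrow(gd), 1L)
  for (m in c("dominant", "recessive", "codominant", "allelic", "trend")) {
    expect_lt(gd[[paste0("p_", m)]], 0.05)
  }
  expect_true(gd$differentiating)
  expect_equal(gd$nearest_gene_id, "g1")
})

test_that("the genic flank boundary is inclusive at exactly 5 kb", {
  # SNPs 4,999 and 5,001 bp upstream of a gene starting at 100,000
  hap <- rbind(matrix(0L, 20L, 2L), matrix(1L, 20L, 2L))
  ds <- toy_ds(hap, c(94999L, 95001L), rep(c("wild", "farm"), each = 10L))
  genes <- data.frame(id = "g1", chrom = "chr1", start = 100000L,
                      end = 110000L, strand = "+", coverage = NA_real_)
  gd <- scan_differentiated_loci(ds, "farm", "wild", genes = genes)
  expect_equal(gd$gene_distance[match(c(95001L, 94999L), gd$pos)],
               c(4999, 5001))
  expect_equal(gd$in_genic_flank[match(c(95001L, 94999L), gd$pos)],
               c(TRUE, FALSE))
  expect_equal(gd$differentiating[match(c(95001L, 94999L), gd$pos)],
               c(TRUE, FALSE))
})

test_that("monomorphic sites are skipped and orientation is wild-major", {
  hap <- cbind(rep(0L, 40L),                      # monomorphic -> skipped
               c(rep(0L, 38L), 1L, 1L))          # polymorphic
  ds <- toy_ds(hap, c(1000L, 2000L), rep(c("wild", "farm"), each = 10L))
  gd <- suppressMessages(scan_differentiated_loci(ds, "farm", "wild"))
  expect_equal(gd$pos, 2000L)
  # wild-major orientation: flipping all alleles leaves p-values unchanged
  ds_flip <- toy_ds(1L - hap[, 2L, drop = FALSE], 2000L,
                    rep(c("wild", "farm"), each = 10L))
  gd_flip <- scan_differentiated_loci(ds_flip, "farm", "wild")
  for (m in c("dominant", "recessive", "codominant", "allelic", "trend")) {
    expect_equal(gd[[paste0("p_", m)]], gd_flip[[paste0("p_", m)]])
  }
})

test_that("candidate-bin membership is recorded per locus", {
  hap <- rbind(matrix(0L, 20L, 2L), matrix(1L, 20L, 2L))
  ds <- toy_ds(hap, c(10000L, 60000L), rep(c("wild", "farm"), each = 10L))
  cand <- data.frame(chrom = "chr1", start = c(1L, 50001L),
                     end = c(50001L, 100001L),
                     is_candidate = c(TRUE, FALSE))
  gd <- scan_differentiated_loci(ds, "farm", "wild",
                                 candidate_bins = cand)
  expect_equal(gd$in_candidate_bin, c(TRUE, FALSE))
})
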