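test_that("EHH decay matches hand-enumerated pair counts", {
  # identical haplotypes: EHH stays 1
  hap <- matrix(0L, nrow = 4L, ncol = 5L)
  d <- ehh_decay(hap, c(10, 20, 30, 40, 50) * 1000, 1L, "downstream")
  expect_equal(d$ehh, rep(1, 5L))
  expect_equal(d$offset, c(0, 10, 20, 30, 40) * 1000)

  # alleles {0,0,1,1} at the first flanking site: 2 identical pairs of 6
  hap2 <- cbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L))
  d2 <- ehh_decay(hap2, c(1000, 2000), 1L, "downstream")
  expect_equal(d2$ehh, c(1, 2 / 6))

  # pairwise-distinct haplotypes: EHH hits 0 and extension stops
  hap3 <- cbind(rep(0L, 4L), c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L),
                rep(0L, 4L))
  d3 <- ehh_decay(hap3, c(1, 2, 3, 4) * 1000, 1L, "downstream")
  expect_equal(nrow(d3), 3L)
  expect_equal(d3$ehh[3L], 0)
})

test_that("EHH equals exhaustive pair comparison on random matrices", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:8, 1L)
    s <- sample(3:12, 1L)
    hap <- random_hap(n, s)
    pos <- sort(sample.int(1e5, s))
    core <- sample.int(s, 1L)
    for (dir in c("downstream", "upstream")) {
      got <- ehh_decay(hap, pos, core, dir, cutoff = 0, max_gap = Inf)
      expect_equal(got$ehh, brute_ehh(hap, core, dir))
    }
  }
})

test_that("EHH decay is non-increasing and truncates at cutoff and gaps", {
  set.seed(31)
  for (rep in 1:20) {
    hap <- random_hap(8L, 20L)
    pos <- sort(sample.int(2e5, 20L))
    d <- ehh_decay(hap, pos, 5L, "downstream", cutoff = 0.2)
    expect_true(all(diff(d$ehh) <= 1e-12))
    if (nrow(d) > 1L) {
      expect_true(all(d$ehh[-nrow(d)] >= 0.2))  # only the last may cross
    }
  }
  # a gap larger than max_gap stops extension before the distant site
  hap <- matrix(0L, 4L, 3L)
  d <- ehh_decay(hap, c(1000, 2000, 300000), 1L, "downstream",
                 max_gap = 10000)
  expect_equal(nrow(d), 2L)
})

test_that("iES integrates the decay curve by trapezoids", {
  flat <- data.frame(offset = c(0, 10000), ehh = c(1, 1))
  none <- data.frame(offset = 0, ehh = 1)
  expect_equal(integrated_ehh(flat, flat), 20000)
  tri <- data.frame(offset = c(0, 1000), ehh = c(1, 0.5))
  expect_equal(integrated_ehh(tri, none), 750)
  tri2 <- data.frame(offset = c(0, 2000), ehh = c(1, 0.5))
  expect_equal(integrated_ehh(tri2, none), 1500)  # doubling offsets
  expect_equal(integrated_ehh(none, none), 0)
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  set.seed(41)
  hap_one <- random_hap(10L, 40L)
  hap <- rbind(hap_one, hap_one)  # farm haplotypes identical to wild
  pos <- sort(sample.int(5e5, 40L))
  ds <- toy_ds(hap, pos, rep(c("wild", "farm"), each = 5L))
  sc <- xpehh_scan(ds, "farm", "wild", min_ies = 0)
  expect_equal(sc$raw_lnratio, rep(0, nrow(sc)))

  sim <- simulate_two_pop(sim_config(seed = 42, genome = c(chr1 = 5e5),
                                     burnin = 300L,
                                     sweep = data.frame(chrom = "chr1",
                                                        pos = 225000,
                                                        s = 0.5)))
  fwd <- xpehh_scan(sim$dataset, "farm", "wild")
  rev <- xpehh_scan(sim$dataset, "wild", "farm")
  shared <- intersect(fwd$pos, rev$pos)
  expect_gt(length(shared), 0L)
  expect_equal(fwd$raw_lnratio[match(shared, fwd$pos)],
               -rev$raw_lnratio[match(shared, rev$pos)])
})

test_that("compiled scan agrees with the single-core reference path", {
  set.seed(51)
  sim <- simulate_two_pop(sim_config(seed = 51, genome = c(chr1 = 3e5),
                                     burnin = 200L, sweep = NULL))
  ds <- sim$dataset
  sc <- xpehh_scan(ds, "farm", "wild")
  cores <- sort(sample(seq_len(nrow(ds$sites)), 12L))
  for (core in cores) {
    ref <- xpehh_site(ds, "farm", "wild", core)
    row <- sc[sc$pos == ds$sites$pos[core], ]
    if (!ref$scoreable) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(row$ies_ref, ref$ies_ref, tolerance = 1e-12)
      expect_equal(row$ies_test, ref$ies_test, tolerance = 1e-12)
    }
  }
})

test_that("a hard sweep gives positive XP-EHH at the swept core", {
  sim <- simulate_two_pop(sim_config(seed = 61, genome = c(chr1 = 1e6),
                                     burnin = 500L,
                                     sweep = data.frame(chrom = "chr1",
                                                        pos = 475000,
                                                        s = 0.5)))
  expect_true(sim$truth$sweep$established)
  sc <- xpehh_scan(sim$dataset, "farm", "wild")
  near <- abs(sc$pos - 475000) < 25000
  expect_gt(mean(sc$raw_lnratio[near]), 0)
})

test_that("score normalization is an exact z-score", {
  z <- normalize_scores(c(-1, 0, 1))
  expect_equal(z, c(-1, 0, 1) / sqrt(2 / 3))
  set.seed(71)
  x <- rnorm(50L)
  expect_equal(normalize_scores(2 * x + 5), normalize_scores(x))
  expect_equal(mean(normalize_scores(x)), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(normalize_scores(x)^2)), 1, tolerance = 1e-9)
  expect_error(normalize_scores(rep(1, 5L)), "degenerate")
  expect_error(normalize_scores(1), "2 finite")
})
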