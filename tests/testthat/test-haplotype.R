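test_that("phased biallelic VCF is read into the expected haplotype matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 c(vcf_rec("chr1", 100, "A", "T", c("0|1", "1|1")),
                   vcf_rec("chr1", 200, "C", "G", c("0|0", "0|1")),
                   vcf_rec("chr1", 300, "G", "A", c("1|0", "0|0"))),
                 c("sA", "sB"))
  ds <- read_phased_vcf(path)
  expect_equal(nrow(ds$haplotypes), 4L)
  expect_equal(nrow(ds$sites), 3L)
  expect_equal(ds$sites$pos, c(100L, 200L, 300L))
  # sample order, each sample contributing (left, right) haplotypes
  expect_equal(unname(ds$haplotypes[, 1L]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(ds$haplotypes[, 3L]), c(1L, 0L, 0L, 0L))
})

test_that("multi-allelic and non-SNP records are excluded, with a log line", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 c(vcf_rec("chr1", 100, "A", "T", c("0|1", "1|1")),
                   vcf_rec("chr1", 150, "A", "T,G", c("0|1", "1|1")),
                   vcf_rec("chr1", 200, "AT", "A", c("0|0", "0|1")),
                   vcf_rec("chr1", 250, "C", "G", c("0|0", "1|1")),
                   vcf_rec("chr1", 300, "G", "A", c("1|0", "0|0"))),
                 c("sA", "sB"))
  expect_message(ds <- read_phased_vcf(path), "excluded 2")
  expect_equal(nrow(ds$sites), 3L)
  expect_equal(ds$sites$pos, c(100L, 250L, 300L))
})

test_that("unphased and missing genotypes violate the input contract", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 c(vcf_rec("chr1", 100, "A", "T", c("0|1", "1|1")),
                   vcf_rec("chr1", 200, "C", "G", c("0/1", "0|1"))),
                 c("sA", "sB"))
  expect_error(read_phased_vcf(path), "chr1:200")

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path2,
                 c(vcf_rec("chr1", 100, "A", "T", c("0|1", ".|."))),
                 c("sA", "sB"))
  expect_error(read_phased_vcf(path2), "missing")
  # escape hatch: fill with the population-major allele
  expect_message(ds <- read_phased_vcf(path2, fill_major = TRUE), "filled 2")
  expect_false(anyNA(ds$haplotypes))
})

test_that("panel restricts and labels samples; absent samples are an error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path,
                 c(vcf_rec("chr1", 100, "A", "T", c("0|1", "1|1", "0|0"))),
                 c("sA", "sB", "sC"))
  panel <- data.frame(sample = c("sA", "sC"),
                      population = c("wild", "farm"))
  ds <- read_phased_vcf(path, panel)
  expect_equal(ds$sample_ids, c("sA", "sC"))
  expect_equal(unname(ds$populations), c("wild", "farm"))
  bad <- data.frame(sample = c("sA", "sZ"), population = c("w", "f"))
  expect_error(read_phased_vcf(path, bad), "sZ")
})

test_that("allele and genotype counts agree with a per-haplotype tally", {
  set.seed(11)
  hap <- random_hap(10L, 30L)
  ds <- toy_ds(hap, seq(100, by = 100, length.out = 30L),
               rep(c("wild", "farm"), c(3L, 2L)))
  ac <- allele_counts(ds, "wild")
  gc <- genotype_counts(ds, "wild")
  wild_rows <- 1:6
  for (j in seq_len(30L)) {
    expect_equal(unname(ac[j, "count1"]), sum(hap[wild_rows, j]))
    expect_equal(unname(ac[j, "count0"]), 6L - sum(hap[wild_rows, j]))
    doses <- hap[c(1L, 3L, 5L), j] + hap[c(2L, 4L, 6L), j]
    expect_equal(unname(gc[j, ]),
                 c(sum(doses == 0L), sum(doses == 1L), sum(doses == 2L)))
  }
  # mutual consistency: allele count derivable from the genotype triple
  expect_equal(unname(2L * gc[, "n_homalt"] + gc[, "n_het"]),
               unname(ac[, "count1"]))
  expect_equal(unname(rowSums(gc)), rep(3L, 30L))
  expect_error(allele_counts(ds, "unknown"), "unknown population")
  expect_error(allele_counts(ds, "wild", 31L), "out of range")
})

test_that("hand-built genotype examples count correctly", {
  hap <- rbind(c(0L), c(0L), c(0L), c(1L), c(1L), c(1L))
  ds <- toy_ds(hap, 100L, rep("p", 3L))
  expect_equal(unname(genotype_counts(ds, "p")[1L, ]), c(1L, 1L, 1L))
  hap2 <- matrix(1L, nrow = 10L, ncol = 1L)
  ds2 <- toy_ds(hap2, 100L, rep("p", 5L))
  expect_equal(unname(allele_counts(ds2, "p")[1L, ]), c(0L, 10L))
  expect_equal(unname(genotype_counts(ds2, "p")[1L, ]), c(0L, 0L, 5L))
})

test_that("write then read is the identity on the haplotype data", {
  set.seed(4)
  sim <- simulate_two_pop(sim_config(seed = 4, genome = c(chr1 = 4e5),
                                     burnin = 300L, sweep = NULL))
  ds <- sim$dataset
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(ds, path)
  panel <- data.frame(sample = ds$sample_ids,
                      population = unname(ds$populations))
  back <- read_phased_vcf(path, panel)
  expect_identical(back$sites$pos, ds$sites$pos)
  expect_identical(back$sites$ref, ds$sites$ref)
  expect_identical(unname(back$haplotypes), unname(ds$haplotypes))
  expect_identical(back$sample_ids, ds$sample_ids)
})

test_that("an empty site list round-trips as a header-only VCF", {
  ds <- haplotype_dataset(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character()),
    matrix(integer(), nrow = 2L, ncol = 0L), "sA",
    c(sA = "wild"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(ds, path)
  expect_true(all(startsWith(readLines(path), "#")))
})

test_that("dataset invariants are enforced", {
  expect_error(toy_ds(matrix(c(0L, 1L, NA, 0L), 2L), c(100L, 200L),
                      "wild"), "missing")
  expect_error(toy_ds(matrix(0L, 2L, 2L), c(200L, 100L), "wild"),
               "strictly increasing")
  expect_error(toy_ds(matrix(2L, 2L, 1L), 100L, "wild"), "0/1")
})
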