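# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive each statistic from its definition
# (exhaustive pair comparison, enumeration) and share no code with the
# package implementations they check.

# EHH at each successive site from the core, by exhaustive comparison of
# every haplotype pair over the growing interval of flanking sites; the
# core site itself carries no allele partition (whole-sample EHH with
# EHH(0) = 1), so the interval starts empty.  No truncation.
brute_ehh <- function(hap, core, direction) {
  n <- nrow(hap)
  step <- if (direction == "downstream") 1L else -1L
  idx <- integer(0)
  out <- 1
  j <- core + step
  while (j >= 1L && j <= ncol(hap)) {
    idx <- c(idx, j)
    same <- 0L
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (all(hap[a, idx] == hap[b, idx])) same <- same + 1L
      }
    }
    out <- c(out, same / (n * (n - 1) / 2))
    j <- j + step
  }
  out
}

# mean pairwise difference per bp between haplotypes over a window
brute_pi <- function(hap, window_bp) {
  n <- nrow(hap)
  if (n < 2L) stop("need >= 2 haplotypes")
  tot <- 0
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) tot <- tot + sum(hap[a, ] != hap[b, ])
  }
  tot / (n * (n - 1) / 2) / window_bp
}

# two-sided Fisher exact p by full enumeration over the hypergeometric
# support of tables with the observed margins
brute_fisher <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L])
  support <- max(0L, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(support, r1, r2, c1)
  pobs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# minimal in-memory dataset from a haplotype matrix (rows = haplotypes,
# two consecutive rows per sample) and positions on one chromosome
toy_ds <- function(hap, pos, pops, chrom = "chr1") {
  nsam <- nrow(hap) / 2L
  ids <- sprintf("s%02d", seq_len(nsam))
  haplotype_dataset(
    data.frame(chrom = chrom, pos = as.integer(pos),
               ref = "A", alt = "T", stringsAsFactors = FALSE),
    hap, ids, stats::setNames(pops, ids))
}

random_hap <- function(n, s) {
  matrix(sample(0:1, n * s, replace = TRUE), nrow = n)
}

# small VCF text fixture written at test time
write_test_vcf <- function(path, records, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
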