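#' Genotype-model contingency table
#'
#' Collapses the genotype triples of two populations into the contingency
#' table of a genetic model.  Dominant, recessive and allelic models yield
#' 2x2 tables; codominant and Cochran-Armitage trend models keep the raw
#' 2x3 genotype table.  Rows are populations; cell totals are conserved
#' (alleles rather than genotypes for the allelic model).
#'
#' @param countsA,countsB genotype triples `(n_homref, n_het, n_homalt)` for
#'   the two populations.
#' @param model one of `"dominant"`, `"recessive"`, `"codominant"`,
#'   `"allelic"`, `"trend"`.
#' @return Integer matrix (2x2 or 2x3) with labelled rows and columns.
#' @export
model_table <- function(countsA, countsB,
                        model = c("dominant", "recessive", "codominant",
                                  "allelic", "trend")) {
  model <- match.arg(model)
  stopifnot(length(countsA) == 3L, length(countsB) == 3L)
  tab3 <- rbind(A = as.integer(countsA), B = as.integer(countsB))
  colnames(tab3) <- c("homref", "het", "homalt")
  switch(model,
    dominant = cbind(carrier = tab3[, "het"] + tab3[, "homalt"],
                     homref = tab3[, "homref"]),
    recessive = cbind(homalt = tab3[, "homalt"],
                      other = tab3[, "het"] + tab3[, "homref"]),
    allelic = cbind(alt = 2L * tab3[, "homalt"] + tab3[, "het"],
                    ref = tab3[, "het"] + 2L * tab3[, "homref"]),
    codominant = tab3,
    trend = tab3)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum over all tables with the
#' observed margins whose point probability does not exceed the observed
#' table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("fisher_exact_2x2 needs a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test for a 2x3 genotype table
#'
#' Plain Pearson statistic without continuity correction.  Genotype classes
#' absent from both populations are dropped, reducing the degrees of
#' freedom to `k - 1` for `k` non-empty classes; with fewer than two
#' non-empty classes the populations are indistinguishable and p = 1.
#'
#' @param table 2x3 matrix of nonnegative integer counts (rows =
#'   populations).
#' @return p-value in (0, 1].
#' @export
chisq_2x3 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) != 3L) {
    stop("chisq_2x3 needs a 2x3 table")
  }
  if (any(rowSums(table) == 0)) stop("a population with zero samples")
  keep <- colSums(table) > 0
  tab <- table[, keep, drop = FALSE]
  if (ncol(tab) < 2L) return(1)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Cochran-Armitage trend test for a 2x3 genotype table
#'
#' Linear-trend test of allele dose with default scores (0, 1, 2); the
#' squared trend statistic is referred to the chi-square distribution with
#' 1 degree of freedom.  The p-value is invariant under affine
#' transformations of the score vector.  Degenerate tables with no trend
#' variance (e.g. all counts in one genotype class) return p = 1 with a
#' warning.
#'
#' @param table 2x3 matrix of nonnegative integer counts (rows =
#'   populations, columns ordered by allele dose).
#' @param weights dose scores for the three genotype classes.
#' @return p-value in (0, 1].
#' @export
cochran_armitage <- function(table, weights = c(0, 1, 2)) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) != 3L) {
    stop("cochran_armitage needs a 2x3 table")
  }
  keep <- colSums(table) > 0
  x <- table[1L, keep]
  n <- colSums(table)[keep]
  w <- weights[keep]
  phat <- sum(x) / sum(n)
  if (length(n) < 2L || phat <= 0 || phat >= 1 ||
      sum(n * (w - sum(n * w) / sum(n))^2) == 0) {
    warning("zero trend variance; p = 1")
    return(1)
  }
  # suppress the lm()-based fitter's spurious perfect-fit warning; only
  # the chi-square statistic is used
  unname(suppressWarnings(stats::prop.trend.test(x, n, score = w))$p.value)
}

diff_models <- c("dominant", "recessive", "codominant", "allelic", "trend")

# p-values of the five genetic models for one pair of genotype triples
model_pvalues <- function(tripleA, tripleB) {
  p <- setNames(numeric(5L), diff_models)
  for (m in c("dominant", "recessive", "allelic")) {
    p[m] <- fisher_exact_2x2(model_table(tripleA, tripleB, m))
  }
  p["codominant"] <- chisq_2x3(model_table(tripleA, tripleB, "codominant"))
  p["trend"] <- suppressWarnings(
    cochran_armitage(model_table(tripleA, tripleB, "trend")))
  p
}

#' Per-SNP genotype-differentiation scan under five genetic models
#'
#' For every polymorphic SNP the wild-vs-farm genotype distributions are
#' tested under the dominant, recessive and allelic models (Fisher exact
#' test on 2x2 tables), the codominant model (chi-square on the 2x3 table)
#' and the Cochran-Armitage trend model.  Tables are oriented by the
#' reference population's major allele, so `homref` always means the
#' wild-major homozygote.  A locus is flagged as differentiating when its
#' smallest model p-value is below `alpha` (no multiplicity correction:
#' the rule is "at least one model", anti-conservative by construction)
#' and the SNP lies inside a gene body or within `flank` bp of one.
#' Monomorphic sites are skipped with a log line.
#'
#' @param ds a [haplotype_dataset()].
#' @param test_pop,ref_pop population labels (farm and wild).
#' @param genes data.frame from [read_gene_annotation()] (optional; without
#'   it the genic-flank flag is FALSE everywhere).
#' @param candidate_bins bin table with an `is_candidate` column (optional).
#' @param alpha significance level on the per-locus minimum p (default
#'   0.05).
#' @param flank genic flank in bp (default 5000).
#' @return data.frame with one row per tested SNP: `chrom`, `pos`, one
#'   `p_<model>` column per model, `p_min`, `nearest_gene_id`,
#'   `gene_distance`, `in_genic_flank`, `in_candidate_bin`,
#'   `differentiating`.
#' @export
scan_differentiated_loci <- function(ds, test_pop, ref_pop, genes = NULL,
                                     candidate_bins = NULL, alpha = 0.05,
                                     flank = 5000) {
  gw <- genotype_counts(ds, ref_pop)
  gf <- genotype_counts(ds, test_pop)
  # orient by the wild major allele; flip triples where alt is wild-major
  flip <- 2L * gw[, "n_homalt"] + gw[, "n_het"] > rowSums(gw)
  gw[flip, ] <- gw[flip, 3:1]
  gf[flip, ] <- gf[flip, 3:1]
  mono <- (gw[, "n_homref"] + gf[, "n_homref"]) == rowSums(gw) + rowSums(gf) |
    (gw[, "n_homalt"] + gf[, "n_homalt"]) == rowSums(gw) + rowSums(gf)
  if (any(mono)) {
    ss_log("genodiff", "%d monomorphic site(s) skipped", sum(mono))
  }
  idx <- which(!mono)
  out <- data.frame(chrom = ds$sites$chrom[idx], pos = ds$sites$pos[idx],
                    stringsAsFactors = FALSE)

  # many SNPs share the same pair of genotype triples; test each pattern once
  key <- apply(cbind(gw[idx, , drop = FALSE], gf[idx, , drop = FALSE]), 1L,
               paste, collapse = ",")
  upat <- !duplicated(key)
  pv <- matrix(NA_real_, nrow = sum(upat), ncol = 5L,
               dimnames = list(NULL, diff_models))
  urows <- idx[upat]
  for (i in seq_along(urows)) {
    pv[i, ] <- model_pvalues(gw[urows[i], ], gf[urows[i], ])
  }
  pmat <- pv[match(key, key[upat]), , drop = FALSE]
  for (m in diff_models) out[[paste0("p_", m)]] <- pmat[, m]
  out$p_min <- do.call(pmin, as.data.frame(pmat))

  out$nearest_gene_id <- NA_character_
  out$gene_distance <- NA_real_
  out$in_genic_flank <- FALSE
  if (!is.null(genes) && nrow(genes)) {
    sgr <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$pos, out$pos))
    ggr <- genes_granges(genes)
    hit <- suppressWarnings(GenomicRanges::distanceToNearest(sgr, ggr))
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    out$nearest_gene_id[q] <- genes$id[s]
    # edge distance in bp (0 inside the gene body), not the gap base count
    out$gene_distance[q] <- pmax(genes$start[s] - out$pos[q],
                                 out$pos[q] - genes$end[s], 0)
    out$in_genic_flank <- !is.na(out$gene_distance) &
      out$gene_distance <= flank
  }
  out$in_candidate_bin <- FALSE
  if (!is.null(candidate_bins)) {
    cand <- candidate_bins[candidate_bins$is_candidate, , drop = FALSE]
    if (nrow(cand)) {
      b <- bin_index_of(cand, out$chrom, out$pos)
      out$in_candidate_bin <- !is.na(b) &
        out$pos >= cand$start[b] & out$pos < cand$end[b]
      out$in_candidate_bin[is.na(out$in_candidate_bin)] <- FALSE
    }
  }
  out$differentiating <- out$p_min < alpha & out$in_genic_flank
  out
}
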