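#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased pairwise estimator: with `n = count0 + count1` haplotypes the
#' per-site diversity is the fraction of the `n(n-1)/2` haplotype pairs that
#' differ, `count0 * count1 / choose(n, 2)` (equivalently `2*p*q*n/(n-1)`).
#'
#' @param count0,count1 nonnegative allele counts (vectorised).
#' @return Numeric vector of per-site diversity values; 0 iff monomorphic.
#' @export
site_pi <- function(count0, count1) {
  n <- count0 + count1
  if (any(n < 2)) stop("site_pi requires at least 2 haplotypes")
  count0 * count1 / (n * (n - 1) / 2)
}

#' Windowed nucleotide diversity per population
#'
#' Sums per-site diversity over the SNPs inside each non-overlapping window
#' and divides by the full window length, giving per-bp diversity.  Windows
#' are anchored at position 1 of each chromosome; the trailing partial window
#' is retained and keeps the full nominal length as denominator.  Windows
#' with no SNP are present with diversity 0.
#'
#' @param ds a [haplotype_dataset()].
#' @param populations population labels to compute; default all present.
#' @param window_size window length in bp (default 50000).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent, each chromosome is tiled out to the window containing its last
#'   SNP.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   half-open `[start, end)`), `n_snps`, and one `pi_<population>` column
#'   per population.
#' @export
windowed_pi <- function(ds, populations = unique(ds$populations),
                        window_size = 50000L, chrom_lengths = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  if (n_sites(ds) == 0L && is.null(chrom_lengths)) {
    stop("empty dataset and no chromosome lengths supplied")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(ds$sites$pos, ds$sites$chrom, max)
    chrom_lengths <- chrom_lengths[unique(ds$sites$chrom)]
  }
  bins <- make_bins(chrom_lengths, window_size)

  pi_site <- lapply(populations, function(p) {
    ac <- allele_counts(ds, p)
    site_pi(ac[, "count0"], ac[, "count1"])
  })
  names(pi_site) <- populations

  bin_of <- bin_index_of(bins, ds$sites$chrom, ds$sites$pos)
  bins$n_snps <- tabulate(bin_of, nbins = nrow(bins))
  for (p in populations) {
    tot <- rep(0, nrow(bins))
    agg <- tapply(pi_site[[p]], bin_of, sum)
    tot[as.integer(names(agg))] <- agg
    bins[[paste0("pi_", p)]] <- tot / window_size
  }
  bins
}

#' Relative nucleotide diversity (wild / farm)
#'
#' Ratio of the reference (wild) population's windowed diversity to the test
#' (farm) population's; values above 1 indicate reduced diversity in the
#' farm population.  Windows where the test population's diversity is zero
#' have no finite ratio: they are marked `defined = FALSE` and excluded from
#' downstream empirical ranking (counted in a log line).
#'
#' @param pi_windows output of [windowed_pi()].
#' @param reference_pop,test_pop population labels.
#' @return `pi_windows` with added columns `ratio` and `defined`.
#' @export
relative_diversity <- function(pi_windows, reference_pop, test_pop) {
  rcol <- paste0("pi_", reference_pop)
  tcol <- paste0("pi_", test_pop)
  if (!rcol %in% names(pi_windows)) {
    stop("unknown population label: ", reference_pop)
  }
  if (!tcol %in% names(pi_windows)) {
    stop("unknown population label: ", test_pop)
  }
  out <- pi_windows
  out$defined <- out[[tcol]] > 0
  out$ratio <- ifelse(out$defined, out[[rcol]] / out[[tcol]], NA_real_)
  n_undef <- sum(!out$defined)
  if (n_undef > 0L) {
    ss_log("pi", "%d window(s) with zero test-population diversity %s",
           n_undef, "excluded from ratio ranking")
  }
  out
}
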