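#' Tile chromosomes into non-overlapping bins
#'
#' Bins are half-open on 1-based coordinates, `[start, start + bin_size)`,
#' anchored at position 1; the last bin of each chromosome may extend past
#' the chromosome end (ceiling division).  Short scaffolds are binned like
#' any chromosome; no length filter is applied.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin length in bp (default 50000).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_bins <- function(chrom_lengths, bin_size = 50000L) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) stop("chrom_lengths must be named")
  pieces <- lapply(chroms, function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    start <- as.integer((seq_len(nb) - 1L) * bin_size + 1L)
    data.frame(chrom = ch, start = start,
               end = as.integer(start + bin_size),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# map positions to bin row indices (NA when the chromosome is absent)
bin_index_of <- function(bins, chrom, pos) {
  key <- paste0(bins$chrom, ":", (bins$start - 1L) %/% (bins$end - bins$start))
  bin_size <- bins$end[1L] - bins$start[1L]
  qkey <- paste0(chrom, ":", (pos - 1L) %/% bin_size)
  match(qkey, key)
}

#' Per-bin representative XP-EHH score
#'
#' Assigns each scored site to its bin and takes the highest raw ln-ratio as
#' the bin's representative score.  Bins without any scored site get `NA`
#' and are excluded from ranking (counted in a log line).  Normalized
#' z-scores across the rankable bins are filled by [normalize_scores()].
#'
#' @param site_scores data.frame as from [xpehh_scan()] (columns `chrom`,
#'   `pos`, `raw_lnratio`).
#' @param bins data.frame as from [make_bins()].
#' @return `bins` with added columns `xpehh_max` and `xpehh_norm`.
#' @export
bin_representative_xpehh <- function(site_scores, bins) {
  bin_of <- bin_index_of(bins, site_scores$chrom, site_scores$pos)
  if (anyNA(bin_of)) {
    stop("scored site(s) on a chromosome absent from the bin grid")
  }
  xpehh_max <- rep(NA_real_, nrow(bins))
  if (nrow(site_scores)) {
    agg <- tapply(site_scores$raw_lnratio, bin_of, max)
    xpehh_max[as.integer(names(agg))] <- agg
  }
  out <- bins
  out$xpehh_max <- xpehh_max
  n_empty <- sum(is.na(xpehh_max))
  if (n_empty > 0L) {
    ss_log("scan", "%d bin(s) without a scored XP-EHH site excluded from %s",
           n_empty, "ranking")
  }
  out$xpehh_norm <- rep(NA_real_, nrow(out))
  scored <- !is.na(xpehh_max)
  if (sum(scored) >= 2L && sd(xpehh_max[scored]) > 0) {
    out$xpehh_norm[scored] <- normalize_scores(xpehh_max[scored])
  }
  out
}

#' Rank-based empirical p-values
#'
#' Upper-tail empirical p: `p_i = #\{ j : value_j >= value_i \} / N` over
#' the `N` non-missing values.  Ties share the larger (conservative) p.
#' `NA` values receive `NA` and do not contribute to `N`.
#'
#' @param values numeric vector of per-bin statistics.
#' @param tail `"upper"` (default) or `"lower"`.
#' @return Numeric vector of p-values in `[1/N, 1]` (NA where input is NA).
#' @export
empirical_p <- function(values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0L) stop("empirical_p on empty input")
  v <- values[ok]
  if (tail == "lower") v <- -v
  # #{ >= v_i } = n - #{ < v_i } ; ties share the larger p
  p <- (n - rank(v, ties.method = "min") + 1) / n
  out <- rep(NA_real_, length(values))
  out[ok] <- p
  out
}

#' Intersect the two genome-scan statistics into candidate sweep bins
#'
#' A bin is a candidate when its empirical p-value is within the top
#' `alpha` fraction for *both* statistics (XP-EHH and relative diversity).
#' Significance is `p * N <= alpha * N`, i.e. the top `floor(alpha * N)`
#' ranks under distinct values; with rank-based p on a continuous statistic
#' this is the p < alpha rule up to ties at the threshold rank.
#'
#' @param bins data.frame carrying columns `p_xpehh` and `p_ratio`.
#' @param alpha empirical significance level (default 0.05).
#' @return `bins` with added logical columns `sig_xpehh`, `sig_ratio`,
#'   `is_candidate`.
#' @export
intersect_candidates <- function(bins, alpha = 0.05) {
  stopifnot(all(c("p_xpehh", "p_ratio") %in% names(bins)))
  out <- bins
  out$sig_xpehh <- !is.na(out$p_xpehh) & out$p_xpehh <= alpha
  out$sig_ratio <- !is.na(out$p_ratio) & out$p_ratio <= alpha
  out$is_candidate <- out$sig_xpehh & out$sig_ratio
  out
}

#' Full bin table for one farm-vs-wild comparison
#'
#' Combines per-site XP-EHH scores and windowed diversity into the per-bin
#' scan table: representative XP-EHH (max raw score per bin), its
#' genome-wide z-score and empirical p, the wild/farm diversity ratio and
#' its empirical p, and the candidate flag from intersecting both at
#' `alpha`.  A bin must be rankable under both statistics to be a candidate.
#'
#' @param site_scores data.frame from [xpehh_scan()].
#' @param rel_div data.frame from [relative_diversity()] on the same grid.
#' @param bins data.frame from [make_bins()].
#' @param alpha empirical significance level.
#' @return Bin table data.frame with columns `chrom`, `start`, `end`,
#'   `n_snps`, `xpehh_max`, `xpehh_norm`, `p_xpehh`, `pi_ratio`, `p_ratio`,
#'   `sig_xpehh`, `sig_ratio`, `is_candidate`.
#' @export
build_bin_table <- function(site_scores, rel_div, bins, alpha = 0.05) {
  tab <- bin_representative_xpehh(site_scores, bins)
  key_b <- paste0(tab$chrom, ":", tab$start)
  key_r <- paste0(rel_div$chrom, ":", rel_div$start)
  m <- match(key_b, key_r)
  if (anyNA(m)) stop("diversity windows do not cover the bin grid")
  tab$n_snps <- rel_div$n_snps[m]
  tab$pi_ratio <- ifelse(rel_div$defined[m], rel_div$ratio[m], NA_real_)
  tab$p_xpehh <- empirical_p(tab$xpehh_max)
  tab$p_ratio <- empirical_p(tab$pi_ratio)
  intersect_candidates(tab, alpha)
}

#' Shared and exclusive candidate bins across populations
#'
#' @param candidate_bins_by_population named list of character vectors of
#'   bin identifiers (e.g. `"chrom:start"`), one per test population.
#' @return List with `shared_all` (bins significant in every population),
#'   `exclusive` (per population, bins in no other population), and
#'   `pairwise` (matrix of pairwise intersection sizes).
#' @export
population_overlap <- function(candidate_bins_by_population) {
  sets <- candidate_bins_by_population
  if (length(sets) < 1L) stop("need at least one bin set")
  shared_all <- Reduce(intersect, sets)
  exclusive <- lapply(seq_along(sets), function(i) {
    setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE))
  })
  names(exclusive) <- names(sets)
  k <- length(sets)
  pairwise <- matrix(NA_integer_, k, k, dimnames = list(names(sets),
                                                        names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  list(shared_all = shared_all, exclusive = exclusive, pairwise = pairwise)
}
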