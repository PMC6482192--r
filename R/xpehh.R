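#' EHH decay curve from a core site
#'
#' Extended haplotype homozygosity at extension distance x is the fraction
#' of haplotype pairs that are identical at all sites from the core out to
#' x inclusive, over all `n(n-1)/2` pairs.  The curve is evaluated at each
#' successive site in the chosen direction; EHH at offset 0 is 1 by
#' convention (the whole-sample curve used for cross-population comparison
#' carries no allele partition at the core).  Extension stops after the
#' first site where EHH drops below `cutoff`, when the gap to the next site
#' exceeds `max_gap`, or at the chromosome end.
#'
#' @param hap integer 0/1 matrix, one row per haplotype, columns ordered by
#'   position; restricted to one chromosome (and typically one population).
#' @param positions physical positions (bp) of the columns, strictly
#'   increasing.
#' @param core column index of the core site.
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param cutoff EHH truncation threshold (default 0.05; 0 disables).
#' @param max_gap largest allowed inter-site gap in bp (default 200000).
#' @return data.frame with columns `offset` (bp from core, nonnegative,
#'   increasing) and `ehh` (non-increasing, `ehh[1] == 1`).
#' @export
ehh_decay <- function(hap, positions, core,
                      direction = c("downstream", "upstream"),
                      cutoff = 0.05, max_gap = 200000) {
  direction <- match.arg(direction)
  n <- nrow(hap)
  if (n < 2L) stop("EHH requires at least 2 haplotypes")
  if (core < 1L || core > ncol(hap)) stop("core site index out of range")
  step <- if (direction == "downstream") 1L else -1L
  npairs <- n * (n - 1) / 2
  group <- rep(1L, n)
  offsets <- 0
  ehh <- 1
  j <- core + step
  prev <- core
  while (j >= 1L && j <= ncol(hap)) {
    if (abs(positions[j] - positions[prev]) > max_gap) break
    group <- match(paste(group, hap[, j]), unique(paste(group, hap[, j])))
    cnt <- tabulate(group)
    e <- sum(cnt * (cnt - 1) / 2) / npairs
    offsets <- c(offsets, abs(positions[j] - positions[core]))
    ehh <- c(ehh, e)
    if (e < cutoff) break
    prev <- j
    j <- j + step
  }
  data.frame(offset = offsets, ehh = ehh)
}

#' Integrated EHH (iES)
#'
#' Trapezoidal area under the EHH decay curve against physical distance,
#' summed over the upstream and downstream directions from the shared core.
#' With no flanking site in either direction the area is 0, below the
#' scoring floor, and the core is treated as unscoreable by [xpehh_site()].
#'
#' @param decay_up,decay_down data.frames from [ehh_decay()] for the two
#'   directions from one core site.
#' @return Numeric area in bp (EHH is dimensionless).
#' @export
integrated_ehh <- function(decay_up, decay_down) {
  trap <- function(d) {
    if (nrow(d) < 2L) return(0)
    sum(diff(d$offset) * (head(d$ehh, -1L) + d$ehh[-1L]) / 2)
  }
  trap(decay_up) + trap(decay_down)
}

# per-population EHH curves evaluated on a fixed site support
# (no truncation: the support was fixed by the pooled-population decay)
ehh_on_support <- function(hap, positions, core, support_idx) {
  n <- nrow(hap)
  npairs <- n * (n - 1) / 2
  group <- rep(1L, n)
  offsets <- 0
  ehh <- 1
  for (j in support_idx) {
    group <- match(paste(group, hap[, j]), unique(paste(group, hap[, j])))
    cnt <- tabulate(group)
    offsets <- c(offsets, abs(positions[j] - positions[core]))
    ehh <- c(ehh, sum(cnt * (cnt - 1) / 2) / npairs)
  }
  data.frame(offset = offsets, ehh = ehh)
}

#' XP-EHH raw score at a single core site
#'
#' Ratio statistic `ln(iES_test / iES_ref)`: positive values indicate longer
#' extended haplotypes (candidate recent selection) in the test (farm)
#' population.  The extension boundary in each direction is determined on
#' the pooled two-population haplotypes, so both integrals share the same
#' support and truncation cannot create ratio artifacts.  Cores where either
#' population's iES falls below `min_ies` are unscoreable.
#'
#' @param ds a [haplotype_dataset()] restricted to one chromosome (see
#'   [subset_chrom()] / [xpehh_scan()] for multi-chromosome data).
#' @param test_pop,ref_pop population labels (farm and wild).
#' @param core_site column index of the core SNP.
#' @param cutoff,max_gap extension controls as in [ehh_decay()], applied to
#'   the pooled curve.
#' @param min_ies scoring floor in bp (default 1).
#' @return List with `ies_ref`, `ies_test`, `raw_lnratio` (NA when
#'   unscoreable) and `scoreable`.
#' @export
xpehh_site <- function(ds, test_pop, ref_pop, core_site,
                       cutoff = 0.05, max_gap = 200000, min_ies = 1) {
  if (length(unique(ds$sites$chrom)) > 1L) {
    stop("xpehh_site expects a single-chromosome dataset")
  }
  rows_t <- pop_hap_rows(ds, test_pop)
  rows_r <- pop_hap_rows(ds, ref_pop)
  if (length(rows_t) < 2L || length(rows_r) < 2L) {
    stop("both populations need at least 2 haplotypes")
  }
  pos <- ds$sites$pos
  pooled <- ds$haplotypes[c(rows_r, rows_t), , drop = FALSE]
  ies <- c(ref = 0, test = 0)
  for (direction in c("downstream", "upstream")) {
    dec <- ehh_decay(pooled, pos, core_site, direction, cutoff, max_gap)
    k <- nrow(dec) - 1L
    step <- if (direction == "downstream") 1L else -1L
    support <- if (k > 0L) core_site + step * seq_len(k) else integer(0)
    for (p in c("ref", "test")) {
      rows <- if (p == "ref") rows_r else rows_t
      cur <- ehh_on_support(ds$haplotypes[rows, , drop = FALSE],
                            pos, core_site, support)
      ies[p] <- ies[p] + integrated_ehh(cur, cur[1L, , drop = FALSE])
    }
  }
  scoreable <- ies["ref"] >= min_ies && ies["test"] >= min_ies
  list(ies_ref = unname(ies["ref"]), ies_test = unname(ies["test"]),
       raw_lnratio = if (scoreable) log(ies[["test"]]) - log(ies[["ref"]])
                     else NA_real_,
       scoreable = scoreable)
}

#' Genome-wide XP-EHH scan
#'
#' Computes the raw XP-EHH ln-ratio at every SNP (compiled scan core,
#' identical construction to [xpehh_site()]).  Unscoreable cores — iES below
#' `min_ies` in either population — are dropped with a log line.
#'
#' @param ds a [haplotype_dataset()] (any number of chromosomes).
#' @param test_pop,ref_pop population labels.
#' @param cutoff,max_gap,min_ies as in [xpehh_site()].
#' @param normalize_sites if TRUE, adds a site-level z-score column
#'   `normalized` (bin-level normalization is the default route; see
#'   [bin_representative_xpehh()]).
#' @return data.frame with columns `chrom`, `pos`, `ies_ref`, `ies_test`,
#'   `raw_lnratio` (one row per scoreable core site).
#' @export
xpehh_scan <- function(ds, test_pop, ref_pop,
                       cutoff = 0.05, max_gap = 200000, min_ies = 1,
                       normalize_sites = FALSE) {
  rows_t <- pop_hap_rows(ds, test_pop)
  rows_r <- pop_hap_rows(ds, ref_pop)
  if (length(rows_t) < 2L || length(rows_r) < 2L) {
    stop("both populations need at least 2 haplotypes")
  }
  out <- list()
  for (ch in unique(ds$sites$chrom)) {
    keep <- which(ds$sites$chrom == ch)
    hap <- ds$haplotypes[c(rows_r, rows_t), keep, drop = FALSE]
    is_test <- rep(c(FALSE, TRUE), c(length(rows_r), length(rows_t)))
    ies <- xpehh_scan_cpp(hap, as.numeric(ds$sites$pos[keep]), is_test,
                          cutoff, max_gap)
    out[[ch]] <- data.frame(chrom = ch, pos = ds$sites$pos[keep],
                            ies_ref = ies[, 1L], ies_test = ies[, 2L],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  scoreable <- res$ies_ref >= min_ies & res$ies_test >= min_ies
  n_drop <- sum(!scoreable)
  if (n_drop > 0L) {
    ss_log("xpehh", "%d core site(s) unscoreable (iES below floor), dropped",
           n_drop)
  }
  res <- res[scoreable, , drop = FALSE]
  rownames(res) <- NULL
  # log difference, so that swapping populations negates the score exactly
  res$raw_lnratio <- log(res$ies_test) - log(res$ies_ref)
  if (normalize_sites) res$normalized <- normalize_scores(res$raw_lnratio)
  res
}

#' Genome-wide score normalization
#'
#' Z-scores against the mean and population (divide-by-n) standard
#' deviation of the input scores; the output has mean 0 and population
#' standard deviation 1.
#'
#' @param scores numeric vector of at least 2 finite values.
#' @return Numeric vector of normalized scores.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 2L || anyNA(scores) || any(!is.finite(scores))) {
    stop("normalize_scores needs >= 2 finite scores")
  }
  s <- sqrt(mean((scores - mean(scores))^2))
  if (s == 0) stop("degenerate score set: zero variance")
  (scores - mean(scores)) / s
}
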