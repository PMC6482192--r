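#' Phased haplotype dataset
#'
#' Container for phased, complete, biallelic SNP genotypes from one or more
#' populations.  Every statistic in the package operates on this structure.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based bp), `ref`, `alt` (single-character alleles).  Within each
#'   chromosome positions must be strictly increasing.
#' @param haplotypes integer matrix of allele states in \{0, 1\}; one row per
#'   haplotype (two consecutive rows per diploid sample, in sample order),
#'   one column per site.  No missing values: input data are assumed
#'   imputed and phased upstream.
#' @param sample_ids character vector of sample identifiers.
#' @param populations named character vector mapping each sample id to its
#'   population label.
#'
#' @return An object of class `haplotype_dataset`.
#' @export
haplotype_dataset <- function(sites, haplotypes, sample_ids, populations) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (anyNA(haplotypes)) {
    stop("haplotype matrix contains missing allele states; ",
         "input must be phased and complete")
  }
  if (length(haplotypes) && !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype matrix must contain only 0/1 allele states")
  }
  if (ncol(haplotypes) != nrow(sites)) {
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ",
         nrow(sites), " sites")
  }
  if (nrow(haplotypes) != 2L * length(sample_ids)) {
    stop("haplotype row count (", nrow(haplotypes),
         ") must equal 2 x sample count (", length(sample_ids), ")")
  }
  if (!all(sample_ids %in% names(populations))) {
    stop("every sample must be assigned to a population")
  }
  populations <- populations[sample_ids]
  if (nrow(sites)) {
    if (any(sites$pos < 1L)) stop("positions must be >= 1")
    for (ch in unique(sites$chrom)) {
      p <- sites$pos[sites$chrom == ch]
      if (is.unsorted(p, strictly = TRUE)) {
        stop("positions on chromosome ", ch,
             " are not strictly increasing")
      }
    }
  }
  structure(
    list(sites = sites, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         populations = populations),
    class = "haplotype_dataset")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat("haplotype_dataset:", nrow(x$sites), "SNPs on",
      length(unique(x$sites$chrom)), "chromosome(s);",
      length(x$sample_ids), "diploid samples (",
      nrow(x$haplotypes), "haplotypes) in populations:",
      paste(sprintf("%s (n=%d)", names(table(x$populations)),
                    table(x$populations)), collapse = ", "), "\n")
  invisible(x)
}

n_sites <- function(ds) nrow(ds$sites)
n_samples <- function(ds) length(ds$sample_ids)

#' Haplotype row indices belonging to a population
#'
#' @param ds a [haplotype_dataset()].
#' @param population population label.
#' @return Integer vector of row indices into `ds$haplotypes`.
#' @export
pop_hap_rows <- function(ds, population) {
  if (!population %in% ds$populations) {
    stop("unknown population: ", population)
  }
  keep <- which(ds$populations == population)
  sort(c(2L * keep - 1L, 2L * keep))
}

#' Population panel file reader
#'
#' Reads a two-column whitespace/TSV file `sample<TAB>population`.
#'
#' @param path file path.
#' @return data.frame with columns `sample` and `population`.
#' @export
read_panel <- function(path) {
  panel <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("sample", "population"))
  if (anyDuplicated(panel$sample)) {
    stop("duplicate sample in panel: ",
         panel$sample[duplicated(panel$sample)][1])
  }
  panel
}

#' Read phased biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file, retains biallelic SNP records only (multi-allelic
#' and non-SNP records are dropped and counted in a log line), and builds the
#' phased haplotype matrix.  All genotypes of retained records must be phased
#' (`0|1` style); missing genotypes are an error because the pipeline's input
#' contract is imputed, phased data.
#'
#' @param path VCF file (plain or gzipped).
#' @param panel optional data.frame as from [read_panel()]; the dataset is
#'   restricted to panel samples and labelled with their populations.  When
#'   absent, all samples are read into a single population `"all"`.
#' @param fill_major escape hatch: if TRUE, missing genotypes are filled with
#'   the population-major allele (counted in a log line) instead of erroring.
#' @return A [haplotype_dataset()].
#' @export
read_phased_vcf <- function(path, panel = NULL, fill_major = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF has no sample genotypes")
  samples <- colnames(gt)[-1L]

  if (!is.null(panel)) {
    missing_s <- setdiff(panel$sample, samples)
    if (length(missing_s)) {
      stop("panel sample(s) absent from VCF header: ",
           paste(missing_s, collapse = ", "))
    }
    samples <- panel$sample
    populations <- setNames(panel$population, panel$sample)
  } else {
    populations <- setNames(rep("all", length(samples)), samples)
  }

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0L) {
    ss_log("read", "excluded %d multi-allelic / non-SNP record(s)", n_drop)
  }
  keep <- which(is_snp)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])

  # GT is the first colon-separated FORMAT field
  gtstr <- sub(":.*$", "", gt[keep, samples, drop = FALSE])
  dim(gtstr) <- c(length(keep), length(samples))
  miss <- is.na(gtstr) | array(grepl("\\.", gtstr), dim(gtstr))
  if (any(miss)) {
    if (!fill_major) {
      i <- which(miss, arr.ind = TRUE)[1L, ]
      stop("missing genotype at ", chrom[i[1L]], ":", pos[i[1L]],
           " sample ", samples[i[2L]],
           "; input must be imputed (or use fill_major = TRUE)")
    }
  }
  phased_ok <- array(grepl("^[01.]\\|[01.]$", gtstr), dim(gtstr))
  if (!all(phased_ok | miss)) {
    i <- which(!(phased_ok | miss), arr.ind = TRUE)[1L, ]
    stop("unphased or malformed genotype '", gtstr[i[1L], i[2L]],
         "' at ", chrom[i[1L]], ":", pos[i[1L]],
         " sample ", samples[i[2L]])
  }

  nsite <- length(keep)
  nsam <- length(samples)
  hap <- matrix(NA_integer_, nrow = 2L * nsam, ncol = nsite)
  a1 <- substr(gtstr, 1L, 1L)
  a2 <- substr(gtstr, 3L, 3L)
  a1[a1 == "."] <- NA
  a2[a2 == "."] <- NA
  for (j in seq_len(nsam)) {
    hap[2L * j - 1L, ] <- as.integer(a1[, j])
    hap[2L * j, ] <- as.integer(a2[, j])
  }

  if (anyNA(hap) && fill_major) {
    n_filled <- 0L
    for (pp in unique(populations)) {
      rows <- which(rep(populations[samples], each = 2L) == pp)
      sub <- hap[rows, , drop = FALSE]
      na_cols <- which(colSums(is.na(sub)) > 0L)
      for (cc in na_cols) {
        col <- sub[, cc]
        major <- as.integer(mean(col, na.rm = TRUE) >= 0.5)
        n_filled <- n_filled + sum(is.na(col))
        col[is.na(col)] <- major
        sub[, cc] <- col
      }
      hap[rows, ] <- sub
    }
    ss_log("read", "filled %d missing allele(s) with population-major allele",
           n_filled)
  }

  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  # preserve chromosome order of first appearance; sort sites within chrom
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  hap <- hap[, ord, drop = FALSE]
  haplotype_dataset(sites, hap, samples, populations)
}

#' Write a haplotype dataset as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only FORMAT and phased genotypes.
#' Reading the file back with [read_phased_vcf()] reproduces the positions,
#' alleles and haplotype matrix exactly.
#'
#' @param ds a [haplotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweepscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (ch in unique(ds$sites$chrom)) {
    writeLines(sprintf("##contig=<ID=%s>", ch), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", ds$sample_ids),
                   collapse = "\t"), con)
  if (n_sites(ds)) {
    nsam <- n_samples(ds)
    gt <- matrix("", nrow = n_sites(ds), ncol = nsam)
    for (j in seq_len(nsam)) {
      gt[, j] <- paste0(ds$haplotypes[2L * j - 1L, ], "|",
                        ds$haplotypes[2L * j, ])
    }
    lines <- paste(ds$sites$chrom, ds$sites$pos, ".", ds$sites$ref,
                   ds$sites$alt, ".", "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"),
                   sep = "\t")
    # degenerate single-sample apply returns the same shape; guard nsam == 1
    if (nsam == 1L) {
      lines <- paste(ds$sites$chrom, ds$sites$pos, ".", ds$sites$ref,
                     ds$sites$alt, ".", "PASS", ".", "GT", gt[, 1L],
                     sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Allele counts at sites within a population
#'
#' @param ds a [haplotype_dataset()].
#' @param population population label.
#' @param site_index 1-based site index (column of the dataset); may be a
#'   vector.
#' @return Integer matrix with one row per requested site and columns
#'   `count0`, `count1`; rows sum to twice the population's sample count.
#' @export
allele_counts <- function(ds, population, site_index = seq_len(n_sites(ds))) {
  rows <- pop_hap_rows(ds, population)
  if (any(site_index < 1L | site_index > n_sites(ds))) {
    stop("site index out of range")
  }
  n1 <- colSums(ds$haplotypes[rows, site_index, drop = FALSE])
  cbind(count0 = length(rows) - n1, count1 = n1)
}

#' Genotype counts at sites within a population
#'
#' Diploid genotype triples with respect to the alt allele.
#'
#' @inheritParams allele_counts
#' @return Integer matrix with one row per requested site and columns
#'   `n_homref`, `n_het`, `n_homalt`; rows sum to the population's sample
#'   count, and `2 * n_homalt + n_het` equals the population alt-allele count.
#' @export
genotype_counts <- function(ds, population,
                            site_index = seq_len(n_sites(ds))) {
  if (!population %in% ds$populations) {
    stop("unknown population: ", population)
  }
  if (any(site_index < 1L | site_index > n_sites(ds))) {
    stop("site index out of range")
  }
  keep <- which(ds$populations == population)
  h1 <- ds$haplotypes[2L * keep - 1L, site_index, drop = FALSE]
  h2 <- ds$haplotypes[2L * keep, site_index, drop = FALSE]
  dose <- h1 + h2
  cbind(n_homref = colSums(dose == 0L),
        n_het = colSums(dose == 1L),
        n_homalt = colSums(dose == 2L))
}

#' Restrict a dataset to one chromosome
#' @keywords internal
subset_chrom <- function(ds, chrom) {
  keep <- which(ds$sites$chrom == chrom)
  haplotype_dataset(ds$sites[keep, , drop = FALSE],
                    ds$haplotypes[, keep, drop = FALSE],
                    ds$sample_ids, ds$populations)
}
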