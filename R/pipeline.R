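#' Full selection-scan pipeline for one or more farm populations
#'
#' Runs, for each test (farm) population against the reference (wild)
#' population: the genome-wide XP-EHH scan, windowed diversity and the
#' relative-diversity ratio, per-bin empirical p-values and candidate
#' intersection, gene assignment for candidate bins, and the per-SNP
#' genotype-differentiation scan.  Per population it writes a bin table
#' TSV, a candidate BED, gene lists and the genotype-differentiation
#' table; across populations it writes a shared/exclusive candidate-bin
#' and gene overlap summary, plus a machine-readable JSON manifest of all
#' parameters, input checksums and package version.  All tabular outputs
#' are TSV with a single `#`-prefixed header line; logs go to stderr.
#'
#' @param vcf path to the phased VCF.
#' @param panel path to the `sample<TAB>population` panel file.
#' @param annotation optional BED/GFF3 gene annotation path.
#' @param outdir output directory.
#' @param ref_pop reference (wild) population label.
#' @param test_pops test population labels; default every non-reference
#'   label in the panel.
#' @param bin_size,alpha,flank,cutoff,max_gap,coverage_min scan parameters
#'   (defaults 50000, 0.05, 5000, 0.05, 200000, 0.70).
#' @param chrom_lengths optional named chromosome lengths; inferred from
#'   the data otherwise.
#' @return List with per-population results (`bins`, `genes`, `genodiff`),
#'   the cross-population `overlap` summary and the `manifest`, invisibly;
#'   files are the primary interface.
#' @export
run_full_scan <- function(vcf, panel, annotation = NULL, outdir,
                          ref_pop = "wild", test_pops = NULL,
                          bin_size = 50000L, alpha = 0.05, flank = 5000,
                          cutoff = 0.05, max_gap = 200000,
                          coverage_min = 0.70, chrom_lengths = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pan <- read_panel(panel)
  if (!ref_pop %in% pan$population) {
    stop("stage panel: reference population '", ref_pop, "' not in panel")
  }
  if (is.null(test_pops)) {
    test_pops <- setdiff(unique(pan$population), ref_pop)
  }
  ss_log("run", "scanning %d test population(s) against '%s'",
         length(test_pops), ref_pop)
  ds <- read_phased_vcf(vcf, pan)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(ds$sites$pos, ds$sites$chrom, max)
    chrom_lengths <- chrom_lengths[unique(ds$sites$chrom)]
  }
  bins <- make_bins(chrom_lengths, bin_size)
  genes <- if (!is.null(annotation)) read_gene_annotation(annotation)
           else NULL

  write_tsv <- function(df, path) {
    cat("#", paste(names(df), collapse = "\t"), "\n", sep = "", file = path)
    suppressWarnings(
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE, append = TRUE, na = "NA"))
    path
  }

  results <- list()
  for (tp in test_pops) {
    ss_log("run", "population %s: XP-EHH scan", tp)
    scores <- xpehh_scan(ds, tp, ref_pop, cutoff = cutoff,
                         max_gap = max_gap)
    ss_log("run", "population %s: windowed diversity", tp)
    pw <- windowed_pi(ds, c(ref_pop, tp), window_size = bin_size,
                      chrom_lengths = chrom_lengths)
    rd <- relative_diversity(pw, ref_pop, tp)
    tab <- build_bin_table(scores, rd, bins, alpha = alpha)
    gb <- NULL
    if (!is.null(genes)) {
      gb <- genes_for_bins(tab[tab$is_candidate, , drop = FALSE], genes,
                           coverage_min = coverage_min,
                           apply_coverage_filter = FALSE)
      go_genes <- genes_for_bins(tab[tab$is_candidate, , drop = FALSE],
                                 genes, coverage_min = coverage_min,
                                 apply_coverage_filter = TRUE)
    }
    ss_log("run", "population %s: genotype differentiation", tp)
    gd <- scan_differentiated_loci(ds, tp, ref_pop, genes = genes,
                                   candidate_bins = tab, alpha = alpha,
                                   flank = flank)

    write_tsv(tab, file.path(outdir, paste0("bins_", tp, ".tsv")))
    cand <- tab[tab$is_candidate, , drop = FALSE]
    bed <- data.frame(chrom = cand$chrom, start = cand$start - 1L,
                      end = pmin(cand$end - 1L,
                                 chrom_lengths[cand$chrom]),
                      name = sprintf("candidate_%d", seq_len(nrow(cand))),
                      score = round(cand$xpehh_norm, 4))
    write_tsv(bed, file.path(outdir, paste0("candidates_", tp, ".bed")))
    if (!is.null(gb)) {
      write_tsv(gb, file.path(outdir, paste0("genes_", tp, ".tsv")))
      writeLines(sort(unique(stats::na.omit(go_genes$gene_id))),
                 file.path(outdir, paste0("gene_list_", tp, ".txt")))
    }
    write_tsv(gd, file.path(outdir, paste0("genodiff_", tp, ".tsv")))
    results[[tp]] <- list(bins = tab, genes = gb, genodiff = gd)
  }

  overlap <- summarize_overlap(results)
  write_tsv(overlap$bins, file.path(outdir, "overlap_bins.tsv"))
  write_tsv(overlap$genes, file.path(outdir, "overlap_genes.tsv"))

  manifest <- list(
    inputs = list(vcf = unname(tools::md5sum(vcf)),
                  panel = unname(tools::md5sum(panel)),
                  annotation = if (!is.null(annotation))
                    unname(tools::md5sum(annotation)) else NA),
    parameters = list(ref_pop = ref_pop, test_pops = test_pops,
                      bin_size = bin_size, alpha = alpha, flank = flank,
                      ehh_cutoff = cutoff, max_gap = max_gap,
                      coverage_min = coverage_min),
    n_snps = n_sites(ds),
    package_version = as.character(packageVersion("sweepscan")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, overlap = overlap,
                 manifest = manifest))
}

#' Cross-population candidate overlap summary
#'
#' Shared and population-exclusive candidate bins and candidate genes
#' across the per-population scan results.
#'
#' @param results named list of per-population results as produced by
#'   [run_full_scan()] (each with a `bins` table and optionally `genes`).
#' @return List with `bins` and `genes` summary data.frames and the raw
#'   [population_overlap()] structures.
#' @export
summarize_overlap <- function(results) {
  if (length(results) < 1L) stop("no population results")
  grids <- lapply(results, function(r) {
    paste0(r$bins$chrom, ":", r$bins$start)
  })
  if (length(unique(grids)) != 1L) {
    stop("population reports are not on the same bin grid")
  }
  bin_sets <- lapply(results, function(r) {
    b <- r$bins
    paste0(b$chrom, ":", b$start)[b$is_candidate]
  })
  ob <- population_overlap(bin_sets)
  bins_df <- data.frame(
    population = c(names(results), "all"),
    n_candidate = c(vapply(bin_sets, length, 1L), NA),
    n_exclusive = c(vapply(ob$exclusive, length, 1L), NA),
    n_shared_all = c(rep(NA, length(results)), length(ob$shared_all)))

  gene_sets <- lapply(results, function(r) {
    if (is.null(r$genes)) character(0)
    else sort(unique(stats::na.omit(r$genes$gene_id)))
  })
  og <- population_overlap(gene_sets)
  genes_df <- data.frame(
    population = c(names(results), "all"),
    n_genes = c(vapply(gene_sets, length, 1L), NA),
    n_exclusive = c(vapply(og$exclusive, length, 1L), NA),
    n_shared_all = c(rep(NA, length(results)), length(og$shared_all)))
  list(bins = bins_df, genes = genes_df, bin_overlap = ob,
       gene_overlap = og)
}
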