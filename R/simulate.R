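#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: a wild reference
#' population and a farm population founded from it through a bottleneck
#' and then exposed to strong artificial selection, sampled at 10 diploids
#' each, on a desk-scale toy genome (one 5 Mb chromosome).  Mutation and
#' recombination rates are scaled up relative to vertebrate per-generation
#' rates so that a small simulated population carries realistic SNP density
#' (about one SNP per kb in the pooled sample) and sub-50 kb linkage
#' structure.
#'
#' @param n_wild,n_farm diploid sample sizes (default 10 each).
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate.
#' @param ancestral_Ne ancestral (and wild) diploid population size.
#' @param farm_founders farm founding bottleneck size (diploids).
#' @param farm_Ne farm census size after founding (default `ancestral_Ne`:
#'   the bottleneck is the founding event, after which the farm is
#'   maintained at ordinary census size).
#' @param generations_farm generations since farm founding.
#' @param sweep data.frame with columns `chrom`, `pos`, `s`: hard-sweep
#'   loci introduced de novo at farm founding with genic selection
#'   (fitness 1, 1 + s/2, 1 + s per genotype).  `NULL` for a fully neutral
#'   split.
#' @param burnin ancestral burn-in generations (default `5 * ancestral_Ne`).
#' @param max_restarts restarts allowed when a sweep allele is lost
#'   (conditioning on establishment).
#' @param seed mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_wild = 10L, n_farm = 10L,
                       genome = c(chr1 = 5e6),
                       mu = 2e-7, rec = 1e-7,
                       ancestral_Ne = 200L, farm_founders = 50L,
                       farm_Ne = ancestral_Ne, generations_farm = 50L,
                       sweep = data.frame(chrom = "chr1", pos = 2475000,
                                          s = 0.5),
                       burnin = 5L * ancestral_Ne,
                       max_restarts = 100L, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(mu >= 0, rec >= 0, all(genome >= 1), !is.null(names(genome)))
  if (!is.null(sweep) && nrow(sweep)) {
    stopifnot(all(sweep$chrom %in% names(genome)),
              all(sweep$pos >= 1 & sweep$pos <= genome[sweep$chrom]),
              all(sweep$s >= 0))
  }
  structure(list(n_wild = as.integer(n_wild), n_farm = as.integer(n_farm),
                 genome = genome, mu = mu, rec = rec,
                 ancestral_Ne = as.integer(ancestral_Ne),
                 farm_founders = as.integer(farm_founders),
                 farm_Ne = as.integer(farm_Ne),
                 generations_farm = as.integer(generations_farm),
                 sweep = sweep, burnin = as.integer(burnin),
                 max_restarts = as.integer(max_restarts),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# strictly increasing integer positions from sorted continuous positions
as_int_positions <- function(p) {
  ip <- as.integer(ceiling(p))
  ip[ip < 1L] <- 1L
  if (length(ip) > 1L) {
    for (i in 2:length(ip)) if (ip[i] <= ip[i - 1L]) ip[i] <- ip[i - 1L] + 1L
  }
  ip
}

#' Simulate a phased wild/farm dataset with known sweep truth
#'
#' Forward Wright-Fisher simulation per chromosome: the ancestral
#' population is burnt in to near mutation-drift balance, then splits; the
#' wild lineage continues neutrally while the farm lineage passes through a
#' founder bottleneck and `generations_farm` generations of genic selection
#' on each sweep locus (introduced de novo in one founder haplotype;
#' establishment is conditioned on by restarting).  The emitted dataset is
#' phased and complete, on a shared site list with combined-sample
#' monomorphic sites removed.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [haplotype_dataset()], populations
#'   `"wild"` and `"farm"`) and `truth` (list with `sweep` — per-locus
#'   position, selection coefficient, final farm allele frequency,
#'   establishment flag, containing 50 kb bin — and `pi_windows`, the
#'   realized windowed diversity of both populations).
#' @export
simulate_two_pop <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nucs <- c("A", "C", "G", "T")
  sites_l <- list()
  haps_l <- list()
  sweep_rows <- list()
  for (ch in names(config$genome)) {
    sw <- config$sweep
    sw <- if (is.null(sw)) sw else sw[sw$chrom == ch, , drop = FALSE]
    spos <- if (is.null(sw)) numeric(0) else as.numeric(sw$pos)
    ss <- if (is.null(sw)) numeric(0) else as.numeric(sw$s)
    res <- wf_sim_chrom_cpp(config$genome[[ch]], config$ancestral_Ne,
                            config$mu, config$rec, config$burnin,
                            config$n_wild, config$n_farm,
                            config$farm_founders, config$farm_Ne,
                            config$generations_farm, spos, ss,
                            config$max_restarts)
    ipos <- as_int_positions(res$pos)
    ref <- nucs[sample.int(4L, length(ipos), replace = TRUE)]
    alt <- nucs[(match(ref, nucs) + sample.int(3L, length(ipos),
                                               replace = TRUE) - 1L) %% 4L +
                1L]
    sites_l[[ch]] <- data.frame(chrom = ch, pos = ipos, ref = ref,
                                alt = alt, stringsAsFactors = FALSE)
    haps_l[[ch]] <- res$haps
    if (length(spos)) {
      m <- match(spos, res$pos)
      sweep_rows[[ch]] <- data.frame(
        chrom = ch, pos = ifelse(is.na(m), NA_integer_, ipos[m]),
        s = ss, farm_freq = res$sweep_freq,
        established = res$sweep_freq > 0,
        restarts = res$restarts, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, sites_l)
  rownames(sites) <- NULL
  haps <- do.call(cbind, haps_l)
  ids <- c(sprintf("wild_%02d", seq_len(config$n_wild)),
           sprintf("farm_%02d", seq_len(config$n_farm)))
  pops <- setNames(rep(c("wild", "farm"), c(config$n_wild, config$n_farm)),
                   ids)
  ds <- haplotype_dataset(sites, haps, ids, pops)

  sweep <- if (length(sweep_rows)) {
    do.call(rbind, c(sweep_rows, list(make.row.names = FALSE)))
  } else NULL
  if (!is.null(sweep)) {
    sweep$bin_start <- as.integer((sweep$pos - 1L) %/% 50000L * 50000L + 1L)
    sweep$bin_id <- ifelse(is.na(sweep$pos), NA_character_,
                           paste0(sweep$chrom, ":", sweep$bin_start))
  }
  pw <- windowed_pi(ds, c("wild", "farm"),
                    chrom_lengths = config$genome)
  list(dataset = ds, truth = list(sweep = sweep, pi_windows = pw))
}

#' Write a complete fixture bundle for the pipeline
#'
#' Emits the simulated phased VCF, a `sample<TAB>population` panel file, a
#' BED gene annotation (uniformly placed genes with one forced to overlap
#' each sweep locus; the BED score column carries the annotation-coverage
#' fraction) and the simulation truth tables.  The bundle is sufficient
#' input for [run_full_scan()].
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param n_genes number of genes to place per chromosome.
#' @param gene_length gene length in bp.
#' @return Named character vector of the written file paths, invisibly;
#'   the simulation result is attached as attribute `"sim"`.
#' @export
emit_fixture_bundle <- function(config, outdir, n_genes = 60L,
                                gene_length = 5000L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_pop(config)
  ds <- sim$dataset
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             panel = file.path(outdir, "panel.tsv"),
             genes = file.path(outdir, "genes.bed"),
             truth_sweep = file.path(outdir, "truth_sweep.tsv"),
             truth_pi = file.path(outdir, "truth_pi.tsv"))
  write_phased_vcf(ds, paths["vcf"])
  write.table(data.frame(sample = ds$sample_ids,
                         population = unname(ds$populations)),
              paths["panel"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  genes <- list()
  gi <- 0L
  for (ch in names(config$genome)) {
    L <- config$genome[[ch]]
    ng <- n_genes
    if (ng > 0L) {
      start <- sort(sample.int(max(1L, as.integer(L - gene_length)), ng))
      sw <- sim$truth$sweep
      if (!is.null(sw)) {
        swp <- sw$pos[sw$chrom == ch & !is.na(sw$pos)]
        for (p in swp) {  # force one gene onto each sweep locus
          k <- which.min(abs(start - p))
          start[k] <- max(1L, as.integer(p - gene_length %/% 2L))
        }
      }
      coverage <- round(runif(ng, 0.5, 1), 3)
      genes[[ch]] <- data.frame(chrom = ch, start0 = start - 1L,
                                end = pmin(start + gene_length - 1L, L),
                                id = sprintf("gene_%03d", gi + seq_len(ng)),
                                coverage = coverage, strand = "+",
                                stringsAsFactors = FALSE)
      gi <- gi + ng
    }
  }
  if (length(genes)) {
    write.table(do.call(rbind, genes), paths["genes"], sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    file.create(paths["genes"])
  }
  sw <- sim$truth$sweep
  if (is.null(sw)) {
    sw <- data.frame(chrom = character(), pos = integer(), s = numeric(),
                     farm_freq = numeric(), established = logical(),
                     restarts = integer(), bin_start = integer(),
                     bin_id = character())
  }
  write.table(sw, paths["truth_sweep"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$pi_windows, paths["truth_pi"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  attr(paths, "sim") <- sim
  invisible(paths)
}
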