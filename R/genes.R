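#' Read a gene annotation from BED or GFF3
#'
#' Coordinates are normalized to the internal 1-based inclusive convention
#' (BED's 0-based half-open intervals are converted on import).  An optional
#' annotation-coverage fraction in `[0, 1]` — the quality of the gene's
#' functional-annotation alignment — is read from the BED score column or a
#' GFF3 `coverage` attribute when present.
#'
#' @param path `.bed`, `.gff` or `.gff3` file.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `coverage` (NA when absent); gene ids are unique.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    grepl("^##gff-version", lines[1L])
  gr <- rtracklayer::import(path, format = if (is_gff) "GFF3" else "BED")
  meta <- as.data.frame(gr)
  if (is_gff) {
    if ("type" %in% names(meta) && any(meta$type == "gene")) {
      meta <- meta[meta$type == "gene", , drop = FALSE]
    }
    id <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) meta$ID
          else meta$Name
    coverage <- if ("coverage" %in% names(meta)) {
      as.numeric(meta$coverage)
    } else NA_real_
  } else {
    id <- meta$name
    coverage <- if ("score" %in% names(meta)) as.numeric(meta$score)
                else NA_real_
  }
  if (is.null(id) || anyNA(id)) stop("gene record(s) without an identifier")
  out <- data.frame(id = as.character(id),
                    chrom = as.character(meta$seqnames),
                    start = meta$start, end = meta$end,
                    strand = as.character(meta$strand),
                    coverage = coverage,
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$coverage) & (out$coverage < 0 | out$coverage > 1))) {
    stop("annotation coverage must be a fraction in [0, 1]")
  }
  if (anyDuplicated(out$id)) {
    stop("duplicate gene id: ", out$id[duplicated(out$id)][1L])
  }
  rownames(out) <- NULL
  out
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end))
}

bins_granges <- function(bins) {
  # bins are half-open [start, end); GRanges are 1-based inclusive
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(bins$start, bins$end - 1L))
}

#' Assign genes to candidate bins
#'
#' Overlap-first with nearest-gene fallback: each candidate bin is assigned
#' every gene overlapping it; a bin with no overlapping gene is assigned the
#' nearest gene on its chromosome by edge distance (ties on both sides are
#' all reported).  Genes whose annotation coverage is below `coverage_min`
#' are excluded when `apply_coverage_filter = TRUE` (genes without a
#' coverage value are always kept).  Strand is ignored for distance.
#'
#' @param bins data.frame of (candidate) bins with `chrom`, `start`, `end`
#'   (half-open).
#' @param genes data.frame from [read_gene_annotation()].
#' @param coverage_min minimum annotation coverage (default 0.70).
#' @param apply_coverage_filter whether to apply the coverage filter
#'   (default TRUE; the filter targets the functional-enrichment export).
#' @return data.frame with one row per (bin, gene) assignment: `chrom`,
#'   `start`, `end`, `gene_id`, `relation` (`"overlap"` or `"nearest"`),
#'   `distance` (bp; 0 for overlaps).  Bins on chromosomes absent from the
#'   annotation are reported with an `NA` gene and a warning.
#' @export
genes_for_bins <- function(bins, genes, coverage_min = 0.70,
                           apply_coverage_filter = TRUE) {
  if (apply_coverage_filter) {
    genes <- genes[is.na(genes$coverage) | genes$coverage >= coverage_min, ,
                   drop = FALSE]
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      relation = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(bins)) return(empty)
  if (!nrow(genes)) {
    warning("no genes in annotation; bins reported without genes")
    return(data.frame(chrom = bins$chrom, start = bins$start,
                      end = bins$end, gene_id = NA_character_,
                      relation = NA_character_, distance = NA_real_,
                      stringsAsFactors = FALSE))
  }
  bgr <- bins_granges(bins)
  ggr <- genes_granges(genes)
  # disjoint seqlevels (bins on unannotated scaffolds) are handled below;
  # suppress GenomicRanges' no-common-seqlevels chatter
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bgr, ggr))
  rows <- data.frame(bin = S4Vectors::queryHits(hits),
                     gene = S4Vectors::subjectHits(hits),
                     relation = rep("overlap", length(hits)),
                     distance = rep(0, length(hits)))
  no_overlap <- setdiff(seq_len(nrow(bins)), unique(rows$bin))
  for (b in no_overlap) {
    same <- which(genes$chrom == bins$chrom[b])
    if (!length(same)) {
      warning("chromosome ", bins$chrom[b], " absent from gene annotation")
      next
    }
    d <- pmax(genes$start[same] - (bins$end[b] - 1L),
              bins$start[b] - genes$end[same], 0)
    nearest <- same[d == min(d)]
    rows <- rbind(rows, data.frame(bin = b, gene = nearest,
                                   relation = "nearest",
                                   distance = min(d)))
  }
  orphan <- setdiff(seq_len(nrow(bins)), unique(rows$bin))
  out <- data.frame(chrom = bins$chrom[rows$bin],
                    start = bins$start[rows$bin],
                    end = bins$end[rows$bin],
                    gene_id = genes$id[rows$gene],
                    relation = rows$relation,
                    distance = rows$distance,
                    stringsAsFactors = FALSE)
  if (length(orphan)) {
    out <- rbind(out, data.frame(chrom = bins$chrom[orphan],
                                 start = bins$start[orphan],
                                 end = bins$end[orphan],
                                 gene_id = NA_character_,
                                 relation = NA_character_,
                                 distance = NA_real_,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(match(out$chrom, unique(bins$chrom)), out$start,
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
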