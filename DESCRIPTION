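Package: sweepscan
Title: Selective Sweep Detection in Paired Wild and Farmed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome scan for signatures of recent artificial selection in a
    domesticated (farm) population relative to a wild reference population.
    Computes cross-population extended haplotype homozygosity (XP-EHH) from
    phased biallelic SNP data, windowed nucleotide diversity and the
    wild-to-farm relative diversity ratio over non-overlapping 50 kb bins,
    rank-based empirical p-values, and their intersection into candidate
    selective-sweep regions.  Candidate bins are annotated with overlapping
    or nearest genes, and per-SNP genotype differentiation is tested under
    five genetic models (dominant, recessive, codominant, allelic and
    Cochran-Armitage trend).  A forward Wright-Fisher simulator with a farm
    founding bottleneck and genic selection provides phased two-population
    datasets with known sweep truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
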