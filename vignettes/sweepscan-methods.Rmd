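---
title: "Detecting artificial selection in farmed populations with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting artificial selection in farmed populations with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Domesticated fish stocks — such as red sea bream bred in Korean and
Japanese farms — experience strong artificial selection over a few dozen
generations. A beneficial allele rising rapidly in frequency drags its
linked neighbourhood with it (genetic hitchhiking), leaving two local
footprints in the farm population relative to its wild source: unusually
*long haplotypes* and *reduced nucleotide diversity*. `sweepscan`
implements a genome scan that reads phased biallelic SNPs for a wild
reference population and one or more farm populations, and intersects two
statistics over non-overlapping 50 kb bins to call candidate selective
sweep regions, then characterises them by gene content and per-SNP
genotype differentiation.

## The two scan statistics

**Cross-population EHH (XP-EHH).** For a core SNP, the extended haplotype
homozygosity at distance $x$ is the fraction of haplotype pairs that are
identical at every SNP between the core and $x$:

$$\mathrm{EHH}(x) = \binom{n}{2}^{-1} \sum_g \binom{n_g}{2},$$

where the $n_g$ are the sizes of the haplotype identity classes over the
flanking interval. The core site itself carries no allele partition
(whole-sample EHH, $\mathrm{EHH}(0)=1$): the statistic compares
populations, not allele classes. Integrating EHH against physical distance
in both directions gives the site's integrated EHH, $iES$, and the raw
score is

$$\mathrm{XP\text{-}EHH} = \ln iES_\text{farm} - \ln iES_\text{wild}.$$

Positive values mean longer haplotypes in the farm population. Two
numerical choices matter:

* *Shared support.* Extension stops where the EHH of the **pooled**
  two-population sample falls below a cutoff (default 0.05), where an
  inter-site gap exceeds `max_gap` (default 200 kb), or at the chromosome
  end. Both integrals therefore run over the same interval, so truncation
  cannot manufacture ratio artifacts. Computing the score as a difference
  of logarithms makes population swap an exact negation in floating point.
* *Scoring floor.* Cores where either population's $iES$ falls below 1 bp
  are unscoreable and dropped (logged), avoiding infinite ratios.

Distance is physical base pairs throughout; no genetic map is used.

**Relative nucleotide diversity.** Per population, windowed diversity is
the sum over SNPs of the unbiased per-site estimator
$c_0 c_1 / \binom{n}{2}$ divided by the full 50 kb window length (per-bp
units; the trailing partial window keeps the nominal denominator, a
conservative choice). The relative diversity of a window is
$\pi_\text{wild} / \pi_\text{farm}$: values above 1 mean the farm lost
diversity there. Windows with $\pi_\text{farm} = 0$ have no finite ratio;
they are excluded from ranking rather than assigned an infinite value,
because rank-based empirical p-values need finite ranks (logged).

## Binning, empirical p-values and candidates

The genome is tiled into half-open 50 kb bins anchored at position 1;
short scaffolds are binned like any chromosome. Each bin's representative
XP-EHH is the **maximum** raw score over its SNPs; a z-score across bins
is reported alongside. Empirical p-values are upper-tail rank fractions,
$p_i = \#\{v_j \ge v_i\}/N$, computed separately for the XP-EHH
representative and the diversity ratio over the bins rankable under each
statistic (ties share the conservative, larger p; the choice of raw or
normalized scores is immaterial because ranks are invariant under
monotone transforms). A bin is a **candidate sweep region** when it is in
the significant tail of *both* statistics at $\alpha = 0.05$. Significance
is implemented as $p \le \alpha$, i.e. exactly the top
$\lfloor \alpha N \rfloor$ ranks under distinct values; on a continuous
statistic this coincides almost surely with the strict $p < \alpha$ rule,
and it makes the marginal significant count exact. No multiple-testing
correction is applied: the scan is a rank-based outlier screen, not a
family of calibrated hypothesis tests.

## Gene assignment

Gene annotations are read from BED or GFF3 (coordinates normalized to
1-based inclusive). Candidate bins are assigned all overlapping genes;
a bin with none is assigned the nearest gene on its chromosome by
nearest-edge coordinate difference, with equidistant ties reported on
both sides. An optional annotation-coverage filter (default 0.70) drops
poorly annotated genes from the functional-enrichment export list only;
genes without a coverage value are kept. Strand is carried but ignored
for distance.

## Genotype differentiation under five genetic models

For every polymorphic SNP the wild and farm genotype triples
$(n_\text{homref}, n_\text{het}, n_\text{homalt})$ are collapsed into
model-specific contingency tables — dominant $(\text{het}+\text{homalt}
\mid \text{homref})$, recessive $(\text{homalt} \mid \text{het}+
\text{homref})$ and allelic (allele counts), each 2×2 and tested with the
two-sided Fisher exact test; codominant (the raw 2×3 table, Pearson
chi-square without continuity correction, empty genotype classes dropped
with the degrees of freedom) and the Cochran–Armitage trend test with
dose scores $(0, 1, 2)$, whose p-value is invariant under affine score
changes. Tables are oriented by the wild population's major allele so
"homref" always means the wild-major homozygote; orientation is a
presentation choice and does not affect any of the five p-values. A locus
is *differentiating* when its minimum model p-value is below 0.05 — the
"at least one model" rule, deliberately uncorrected and therefore
anti-conservative — and the SNP lies in a gene body or within 5 kb of one
(boundary inclusive: 5,000 bp away is in, 5,001 bp is out). Monomorphic
sites are skipped rather than assigned p = 1; the result is identical and
the log notes the count. At 10 + 10 diploids all five tests are
discrete and conservative: their null rejection rates at nominal 0.05
measure around 0.01–0.04 in the package's own calibration run.

## The synthetic-data generator

Because the resequencing data behind the motivating study are not
deposited, every stage is validated on simulated data with known truth.
The generator is a forward Wright–Fisher simulator (compiled core, R
front-end) of diploid individuals as haplotype pairs, random mating with
selfing allowed, infinite-sites mutation on continuous positions, and
Poisson crossovers per meiosis. A single ancestral population of
$N_e = 200$ diploids is burnt in for $5 N_e$ generations (heterozygosity
within ~8% of mutation–drift balance, sufficient for a scan that only
uses relative patterns), then splits:

* the **wild** lineage continues neutrally at census 200;
* the **farm** lineage passes through a founding bottleneck of 50
  broodstock — the bottleneck is the founding *event* — and is then
  maintained at ordinary census size (default 200, `farm_Ne`) for 50
  generations, matching hatchery practice where a limited founder group
  seeds a large maintained stock. A design that instead held the farm at
  census 50 throughout makes post-split drift IBD indistinguishable in
  physical scale from the sweep haplotype and swamps the signal; that is
  a statement about fish-farm demography, not about the statistics.

Each sweep locus is introduced de novo on one founder haplotype at farm
founding and evolves under genic selection (fitness $1, 1+s/2, 1+s$;
default $s = 0.5$ at a bin midpoint, 2,475,000 of a 5 Mb chromosome, so
the bin-level signal is not split across a bin boundary by construction).
Establishment is conditioned on by restarting the farm phase when the
allele is lost. Mutation and recombination rates (default
$\mu = 2\times10^{-7}$, $r = 1\times10^{-7}$ per bp per generation) are
scaled up so the toy genome carries about one SNP per kb in the pooled
sample (~35–40 SNPs per 50 kb bin, enough for stable per-bin diversity)
and sub-50 kb linkage structure. Sampling 10 + 10 diploids yields a
phased, complete dataset on a shared site list with combined-sample
monomorphic sites removed. With `generations_farm = 0` and no sweep the
generator degenerates to a single panmictic pool split into disjoint
samples — the null used for calibration. All randomness flows through R's
RNG, so a seed fixes the dataset bit for bit.

What the generator does *not* emulate: real linkage-map heterogeneity,
gene conversion, migration between farm and wild, polygenic (truncation)
selection, genotyping or phasing error, and reference-genome artifacts.
Green tests therefore demonstrate the pipeline's statistical mechanics
and directional behaviour, not performance on real resequencing data.

## Power under the default study design

With 10 + 10 diploids and ~100 rankable bins, requiring the sweep's bin
to reach the top 5% of *both* statistics is a stringent joint event. In
replicate runs under the default design the sweep bin's diversity ratio
exceeds the genome median in essentially every replicate and reaches the
ratio's top 5% in roughly three quarters; the XP-EHH representative
reaches its top 5% in a bit over half, limited by sampling variance
(per-core $\ln iES$ ratios have null standard deviation ≈ 0.28 at this
sample size), by the max-over-cores representative favouring noisy
background bins, and by post-founding drift IBD patches sharing the
sweep's physical scale. The joint recovery rate is accordingly about one
half. Larger samples or more bins — the regime of the real study, with
thousands of bins genome-wide — raise it; the package reports measured
rates rather than assuming them.

## Problem sizes and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `bin_size` | 50,000 bp | scan window and bin width |
| `alpha` | 0.05 | empirical significance level per statistic |
| `cutoff` | 0.05 | pooled-EHH truncation threshold |
| `max_gap` | 200,000 bp | largest bridgeable inter-site gap |
| `flank` | 5,000 bp | genic flank for differentiating loci |
| `coverage_min` | 0.70 | annotation-coverage filter (GO export list) |
| simulator | 5 Mb, $N_e$ 200, founders 50, $s$ 0.5, 50 gen, 10+10 | study-design emulation |

The EHH cutoff and gap limit are the conventional defaults of the
statistic's reference implementation; the motivating study does not state
them, and both are exposed as configuration. Validation runs in the test
suite use 0.3–2 Mb genomes and shortened burn-ins where only mechanics
are being checked; acceptance-style checks use the full defaults above.

## Known limitations

* Empirical p-values are relative ranks: with pervasive selection the
  top 5% is always 5% of bins, never more, never fewer.
* The per-locus minimum over five model p-values is anti-conservative by
  construction (the motivating design's choice, kept as-is).
* Windows with zero farm diversity — the most extreme sweeps — are
  excluded from the ratio ranking by necessity; in practice residual
  mutations and recombinant edges keep swept 50 kb bins polymorphic.
* The simulator treats chromosomes independently (no cross-chromosome
  fitness linkage) and models hard sweeps only.
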