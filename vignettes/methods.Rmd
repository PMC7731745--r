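---
title: "Windowed paired differential-methylation analysis for RRBS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed paired differential-methylation analysis for RRBS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbsdmr)
```

# The analysis problem

`rrbsdmr` implements a complete reduced-representation bisulfite sequencing
(RRBS) differential-methylation analysis for a *paired* two-group design:
two cell populations — adipogenic and myogenic precursors under the default
labels — isolated from the same animals, three animals in total. The
pipeline runs from per-CpG methylated/unmethylated read counts through
windowed paired testing, CpG-island (CGI) and genomic-feature annotation,
closest-gene linkage, and integration with a gene-expression table to find
*co-different* genes (genes that are simultaneously differentially expressed
and linked to at least one differentially methylated region, DMR).

Because no public sequencing data accompany the study design this package
emulates, a first-class synthetic-data generator produces every input with
planted ground truth, which is what all statistical guarantees in the test
suite are measured against.

# The statistical model

## Per-window paired t-test

Counts are imported in a Bismark-like cytosine-report dialect and collapsed
to CpG dyads (the plus-strand record at position $p$ and the minus-strand
record at $p+1$ report the same CpG and are summed). Sites are kept only if
their depth is strictly greater than 10 in *every* sample and they lie on a
configured autosome set (pig `chr1`–`chr18` by default).

The genome is tiled into fixed-width windows (100 bp, non-overlapping, at
least 3 covered CpGs by default; all configurable). For window $w$ and
sample $s$ the methylation level is the pooled count ratio

$$\beta_{w,s} = \frac{\sum_{i \in w} m_{i,s}}{\sum_{i \in w} n_{i,s}},$$

and the test statistic is a two-sided paired t-test on the per-animal
differences $d_a = \beta_{w,(\text{myogenic},a)} -
\beta_{w,(\text{adipogenic},a)}$ with $n-1$ degrees of freedom. P-values
are Benjamini–Hochberg adjusted in one genome-wide family, and a window is
called a DMR iff

$$|\bar d| \ge 0.03 \quad\text{and}\quad q < 0.05,$$

with direction *hyper* when the myogenic mean is higher. The 3% threshold
is read as 0.03 absolute methylation fraction (percentage points), the only
reading under which a "difference of at least 3%" is well defined for a
proportion.

Two genuinely open choices are resolved as follows and kept configurable:

* **Window geometry.** No window definition is inherent to the method, so
  the package defaults to standard RRBS practice: 100-bp non-overlapping
  tiles with ≥ 3 covered CpGs. An averaged, multi-CpG unit is also what
  makes a 3-percentage-point threshold meaningful.
* **Tested quantity.** The default tests the pooled *level* (coverage
  ratio), which is normalization-free and matches the level-difference call
  threshold. An alternative mode tests size-factor-normalized methylated
  counts (median-of-ratios factors on total coverage, the DESeq estimator).
  With only three pairs (df = 2) the count statistic inherits the depth
  noise and is markedly less powerful: in the packaged simulations it ranks
  planted windows first but does not reach $q<0.05$ at the default depth,
  which is why the level mode is the default. The `delta` used for calling
  is always the level difference in both modes.

Degenerate windows are resolved by the t limit: zero variance with a
non-zero mean difference gives $p = 0$ (the window is called if the delta
threshold passes); zero variance with zero mean gives $p = 1$. With $n = 3$
pairs and discrete counts these cases occur and must be deterministic.

## CpG islands, shores, and genomic features

CGIs follow the classical criteria — length > 200 bp, GC ≥ 0.5, and
observed/expected CpG ratio
$\mathrm{o/e} = N_{\mathrm{CpG}} \cdot L / (N_C \cdot N_G) \ge 0.6$ — via a
two-phase scan: a 200-bp window slides 1 bp at a time and is flagged when
it passes the GC and o/e criteria; overlapping flagged windows are merged;
each merged region (padded by its own span, capped at 2 kb) is then trimmed
to the *maximal* sub-region that still passes all three criteria. Every
emitted island therefore re-verifies the criteria by direct counting — a
hard invariant in the test suite — and on short sequences the detector
agrees with an exhaustive all-subinterval search. N bases are excluded from
all counts and from $L$. Shores are the 2-kb flanks of each island, clipped
to chromosome ends, with island overlap removed and adjacent shores merged.

Gene annotation (GTF, 1-based inclusive, or BED12) is collapsed to one
model per gene using the longest transcript. Features are strand-aware: the
2-kb promoter upstream of the TSS is split into bins P1 (TSS to −200), P2
(−200 to −1500) and P3 (−1500 to −2000); exons and introns are ranked in
transcription order (for a minus-strand gene the promoter lies at genomic
coordinates greater than the TSS and the first exon is the rightmost one).
Each DMR is assigned exactly one category by its midpoint with precedence
promoter P1 > P2 > P3 > 5′UTR > 3′UTR > first exon > other exon > first
intron > other intron > distal intergenic; midpoint assignment guarantees a
partition, so category percentages always sum to 100.

Each DMR is linked to the closest gene by gene-span distance (0 when
overlapping the TSS–TTS span), with ties broken by distance to the TSS and
then lexicographic gene id; linking never crosses chromosomes. Span
distance (rather than TSS distance) is used because distal DMRs are
reported relative to whole genes; the TSS tie-break keeps promoter-proximal
links stable.

## Expression integration

Differentially expressed genes (DEGs) use strict thresholds: fold change
> 2 or < 0.5 and FDR < 0.05. When raw replicates are supplied, the fold
change is the ratio of group means and the FDR comes from a two-sided Welch
t-test on log2 values with BH adjustment — a minimal, transparent stand-in
for an upstream RNA-seq pipeline that is supplied externally in real use.
Co-different genes are exactly the intersection of the DEG set with the
DMR-linked gene set; each receives a quadrant label (hyper-up, hypo-up,
hyper-down, hypo-down) from its expression direction and the methylation
direction of its largest-|delta| linked DMR, while the DMR-level quadrant
tally keeps every link. Fold-change comparisons between hyper- and
hypo-linked genes within a feature category use a two-sided Mann–Whitney
rank-sum test (exact at small sample sizes), chosen for robustness to the
skew of fold-change distributions; arms with fewer than 3 genes are flagged
not testable. Pathway over-representation is a one-sided hypergeometric
upper tail against a user-supplied GMT file within a configurable universe
(all detected genes by default), BH-adjusted across pathways.

# The synthetic-data generator

The generator is the package's substitute for the study's (undeposited)
sequencing data and defines the conditions under which every guarantee is
measured.

* **Genome.** A CpG-depleted background (GC ≈ 0.42, roughly 20% of CpGs
  retained, removed CpGs deaminated C→T) emulates a vertebrate genome.
  Islands are planted as shuffled 21-bp blocks of fixed composition (5 C,
  6 G, 10 A/T; GC 11/21 ≈ 0.524, o/e ≈ 1), flanked by 200-bp CpG-free
  AT-rich insulators. The uniform, slightly super-threshold GC keeps each
  island one contiguous flagged region while bounding how much flank a
  maximal-subinterval call can absorb, so detected boundaries recover the
  planted ones with interval Jaccard ≳ 0.94.
* **Reduced representation.** The genome is digested in silico at every
  CCGG (C^CGG) and fragments of 225–290 bp are retained; only CpGs inside
  kept fragments are observable. Because a depleted background alone yields
  few in-range fragments on a megabase-scale genome, the generator plants
  MspI *target fragments*: CCGG-delimited, CpG-dense (one CpG per ~12 bp),
  AT-leaning (GC ≈ 0.40, below the island criterion) segments whose
  cut-to-cut length falls in the selection range. This mirrors the fact
  that real RRBS coverage concentrates in CpG-dense, MspI-dense subregions,
  at a genome size that simulates in seconds.
* **Methylomes.** True levels start at a 75% baseline, drop to 8% inside
  CGIs, and dip by 80% of baseline within ±500 bp of each TSS. Each animal
  receives a logit-scale random effect (sd 0.05) shared between its two
  cell types — the paired structure that makes the paired t-test the
  natural analysis. DMRs are planted on whole 100-bp windows of the
  analysis grid (±0.40 methylation fraction split evenly between the
  groups, both directions), so sensitivity and FDR are well defined against
  window-aligned truth.
* **Counts.** Per site and sample, depth is negative binomial (mean 50,
  dispersion 0.05; Poisson at dispersion 0) and the methylated count is
  binomial with success probability $m + (1-m)(1-c)$, where $c = 0.995$ is
  the bisulfite conversion rate — failed conversion reads unmethylated
  cytosines as methylated. Non-CpG cytosine control sites (true methylation
  0) are emitted explicitly because a conversion ratio is reported in this
  kind of experiment without a stated estimator; the package estimates it
  as the converted fraction of non-CpG reads, pooled and per sample.
* **Expression.** Log-normal replicate abundances (3 per group), with
  planted DEGs offset by ±2 log2 units in the myogenic group and
  per-replicate noise of 0.25 log2 units.

One top-level seed drives everything; each stage (genome, gene models,
methylome, counts, expression) draws its own deterministic substream, so
identical configurations are byte-identical and regenerating one stage
never perturbs another.

**What the generator does not emulate.** Read alignment and its biases,
strand-specific coverage asymmetry, SNP-induced miscalls, fragment-end
repair artifacts, copy-number variation, and correlated methylation
structure beyond the planted features. Passing tests therefore demonstrate
the correctness and calibration of the *statistics and bookkeeping* under a
faithful generative model of counts — not robustness to alignment-level
artifacts in real libraries.

# Numerical choices and problem sizes

* Null calibration uses the default three-chromosome, 1-Mb-per-chromosome
  study (~1,500 target fragments, ~4,700 tested windows), which gives the
  raw p < 0.05 fraction a Monte-Carlo band of $0.05 \pm 3\sqrt{0.05
  \cdot 0.95 / n}$; recovery runs use twenty 300-kb single-chromosome
  studies with 40 planted DMRs each. These sizes reproduce the study
  conditions (3 pairs, 50× depth, Δ = 0.40, animal sd 0.05) while keeping a
  full simulation in the low seconds.
* BH adjustment delegates to `stats::p.adjust` and is cross-checked in the
  tests against a brute-force step-up implementation; the hypergeometric
  tail uses `stats::phyper` and is cross-checked by direct enumeration.
* Size factors are the median-of-ratios estimator computed on per-site
  total coverage, cross-checked against `DESeq2::estimateSizeFactorsForMatrix`.
  Note the estimator is defined relative to the per-site geometric mean, so
  rescaling one sample by $c$ scales its factor by $c^{1-1/m}$ and all
  factor *ratios* by $c$.
* Methylation fractions are clamped to [0.001, 0.999] before logit
  transforms; window levels with zero pooled coverage are `NA` and such
  windows are excluded from testing with a logged count.
* `find_cgis` pads each merged candidate region by its own span (capped at
  2 kb) before the maximal-subinterval trim; beyond that cap an island
  would have to absorb more than 2 kb of sub-threshold flank, which the GC
  criterion makes impossible for any realistic composition.

# Known limitations

* With three pairs the paired t-test has 2 degrees of freedom; calibration
  holds (the null raw-p fraction sits inside its Monte-Carlo band) but
  power depends strongly on depth, and the normalized-count mode is
  noticeably weaker than the level mode at realistic depths.
* The two-phase island scan can in principle miss islands whose criteria
  hold only over intervals barely longer than 200 bp at razor-thin margins
  (no 200-bp window passes on its own); such knife-edge regions are
  unstable under the criteria themselves.
* The generator's truth is window-aligned by design; it does not model
  DMRs that straddle window boundaries, so reported sensitivity refers to
  window-level recovery.
* The DEG caller's Welch-on-log2 route is a deliberately minimal model for
  replicate expression tables; users with count-level RNA-seq data should
  import results from a dedicated caller and supply the precomputed
  `log2_fc`/`fdr` columns instead.
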