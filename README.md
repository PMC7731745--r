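# rrbsdmr

Windowed paired differential-methylation analysis for reduced-representation
bisulfite sequencing (RRBS), built around a paired two-group design: two cell
populations — adipogenic and myogenic precursors by default — sampled from
the same animals. The package is aimed at analysts who have per-CpG
methylation counts (Bismark-style cytosine reports), a gene annotation, and
an expression table, and who want DMR calls, genomic annotation, and
methylation–expression integration in one reproducible pipeline; and at
methodologists who want a fully synthetic, ground-truthed RRBS study to test
such analyses against.

## The method

For window *w* and sample *s* the methylation level is the pooled count
ratio β(w,s) = Σ m / Σ n over the window's CpG dyads (depth > 10 in every
sample, autosomes only). Each 100-bp window with ≥ 3 covered CpGs is tested
with a two-sided **paired t-test** on the per-animal differences
d(a) = β(myogenic, a) − β(adipogenic, a), df = n−1; p-values are
**Benjamini–Hochberg** adjusted genome-wide, and a window is a DMR iff

    |mean d| ≥ 0.03   and   q < 0.05,

hyper-methylated when the myogenic mean is higher. Around the caller the
package provides:

* a synthetic-data generator: genome with planted CpG islands and MspI
  target fragments, in-silico MspI digestion (C^CGG) with 225–290 bp size
  selection, paired methylomes with planted window-aligned DMRs, negative
  binomial depths, bisulfite-conversion noise (99.5%), non-CpG conversion
  controls, and replicated expression tables with planted DEGs;
* CGI detection by the classical criteria (length > 200 bp, GC ≥ 0.5,
  obs/exp CpG ≥ 0.6; two-phase scan + maximal-subregion trim), 2-kb shores,
  strand-aware promoter bins / UTR / exon / intron annotation with midpoint
  precedence, and closest-gene linkage;
* DEG calling (FC > 2 or < 0.5, FDR < 0.05), co-different genes and
  methylation×expression quadrants, per-category fold-change comparisons
  (exact rank-sum), hypergeometric over-representation against GMT gene
  sets, and a 2^−ΔΔCt utility.

## Worked example

```r
library(rrbsdmr)

cfg <- sim_config(seed = 7, n_chrom = 1, chrom_length = 3e5, n_genes = 20,
                  n_cgi = 5, n_rrbs_targets = 120, n_dmr = 30)
b <- run_pipeline(pipeline_config(sim = cfg, seed = 7), outdir = "results/run1")
print(b)
```

```
[counts] 3186 CpG dyads x 6 samples
[conversion] pooled estimate 0.9950
[filter] 3186 sites survive depth > 10 on autosomes
[windows] 388 windows with >= 3 CpGs
[dmrs] 26 called (14 hyper, 12 hypo)
[cgi] 10 islands, 16 shore intervals
[degs] 15 of 20 genes differentially expressed
RRBS differential-methylation pipeline
  sites: 3186 (3186 after filters); windows tested: 388
  DMRs: 26 (14 hyper, 12 hypo); DEGs: 15; co-different genes: 9
  truth recovery: sensitivity 0.833, empirical FDR 0.038
```

The run simulated a 300-kb study with 30 planted DMRs and 15 planted DEGs;
the caller recovered 25 of the 30 planted windows (sensitivity 0.833) with
one false call among 26 (empirical FDR 0.038), and the conversion-rate
estimator reproduced the simulated 99.5% from the non-CpG controls. The DMR
set prints its direction partition the way such studies report it:

```r
print(b$dmrs)
#> dmr_set: 26 DMRs from 388 tested windows (|delta| >= 0.03, q < 0.05)
#>   hyper in myogenic: 14 (53.8%); hypo: 12 (46.2%)

head(as.data.frame(b$dmrs)[, c("dmr_id", "delta", "q_value", "direction")], 3)
#>                   dmr_id      delta     q_value direction
#> 1   DMR_chr1_16100_16200 -0.4039920 0.031173581      hypo
#> 2   DMR_chr1_76700_76800  0.3860446 0.006140784     hyper
#> 3 DMR_chr1_122000_122100  0.3924879 0.041743913     hyper
```

`delta` is the myogenic-minus-adipogenic methylation difference of the
window (here ≈ ±0.4, the planted effect), `q_value` the BH-adjusted paired-t
p-value. `outdir` receives DMRs/CGIs/shores as BED6, window tests,
annotation, integration and ORA tables as TSV, DMR sequences as multi-FASTA
(for external motif tools), and a structured-text summary. Real data enter
through the same `pipeline_config()` with `counts_paths` (one cytosine
report per sample), `genome_fasta`, `annotation` (GTF/BED12) and
`expression` instead of `sim`; an exported simulated study re-imported this
way reproduces the simulate-mode results exactly.

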