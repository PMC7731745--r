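Package: rrbsdmr
Title: Windowed Paired Differential Methylation Analysis for RRBS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of reduced-representation bisulfite
    sequencing (RRBS) experiments with a paired two-group design, built
    around adipogenic versus myogenic precursor methylomes. Provides an
    in-silico MspI digest and size selection, a synthetic methylome and
    expression generator with planted ground truth, per-CpG count import
    in a Bismark-like cytosine-report dialect, depth and autosome
    filtering, median-of-ratios size factors, fixed-width window tiling
    with a paired t-test and Benjamini-Hochberg correction for calling
    differentially methylated regions (DMRs), CpG-island and genomic
    feature annotation with closest-gene linkage, and integration with
    expression tables to identify co-different genes, quadrant labels and
    hypergeometric pathway over-representation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
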