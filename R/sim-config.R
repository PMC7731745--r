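#' Simulation configuration
#'
#' Builds and validates the configuration object driving the synthetic RRBS
#' study generator. The defaults describe the emulated experiment: two cell
#' populations (adipogenic and myogenic precursors) sampled from the same
#' three animals (a paired design), per-CpG sequencing depth around 50x,
#' bisulfite conversion of 99.5%, a mostly methylated genome (75%) with
#' hypomethylated CpG islands and a methylation dip around transcription
#' start sites, planted differentially methylated windows in both directions,
#' and planted differentially expressed genes at |log2 FC| = 2.
#'
#' @param seed integer seed; all stage-level randomness derives from it.
#' @param n_chrom,chrom_length number of simulated autosomes and their length
#'   in bp (chromosomes are named `chr1`, `chr2`, ...).
#' @param n_genes number of gene models to place.
#' @param n_cgi number of CpG islands to plant.
#' @param cgi_length_range min/max planted CGI length in bp.
#' @param background_gc target GC fraction of the genomic background.
#' @param cpg_depletion fraction of background CpG dinucleotides retained
#'   (in (0, 1]; lower values mean stronger depletion, as in vertebrate
#'   genomes where most CpGs are lost to deamination).
#' @param n_rrbs_targets number of planted MspI target fragments (CCGG to
#'   CCGG, 225-290 bp) providing the CpG-dense reduced representation.
#' @param n_animals animals per group; both cell types come from each animal.
#' @param groups labels of the two cell populations; differences are always
#'   reported as `groups[2]` minus `groups[1]`.
#' @param mean_depth,depth_dispersion per-CpG read depth model: negative
#'   binomial with this mean and dispersion (0 = Poisson).
#' @param conversion_rate bisulfite conversion rate.
#' @param baseline_methylation genome-wide true methylation level.
#' @param cgi_methylation true level inside CpG islands.
#' @param tss_dip_depth,tss_dip_halfwidth relative depression of methylation
#'   (fraction of baseline removed) within `tss_dip_halfwidth` bp of a TSS.
#' @param n_dmr number of differentially methylated windows to plant.
#' @param dmr_delta planted group difference in methylation fraction.
#' @param dmr_window width in bp of the window grid truth is planted on.
#' @param animal_sd sd of the per-animal random effect on the logit scale,
#'   shared between the two cell types of the same animal.
#' @param n_controls number of non-CpG cytosine control sites emitted for
#'   conversion-rate estimation.
#' @param n_deg,deg_log2fc planted differentially expressed genes and their
#'   absolute log2 fold change.
#' @param expr_noise_sd per-replicate sd on the log2 expression scale.
#' @param n_expr_reps expression replicates per group.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 2e5,
#'                   n_rrbs_targets = 40, n_genes = 10, n_cgi = 4)
#' cfg$groups
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L,
                       chrom_length = 1e6,
                       n_genes = 120L,
                       n_cgi = 30L,
                       cgi_length_range = c(800L, 1600L),
                       background_gc = 0.42,
                       cpg_depletion = 0.2,
                       n_rrbs_targets = 1500L,
                       n_animals = 3L,
                       groups = c("adipogenic", "myogenic"),
                       mean_depth = 50,
                       depth_dispersion = 0.05,
                       conversion_rate = 0.995,
                       baseline_methylation = 0.75,
                       cgi_methylation = 0.08,
                       tss_dip_depth = 0.8,
                       tss_dip_halfwidth = 500L,
                       n_dmr = 100L,
                       dmr_delta = 0.40,
                       dmr_window = 100L,
                       animal_sd = 0.05,
                       n_controls = 4000L,
                       n_deg = 15L,
                       deg_log2fc = 2,
                       expr_noise_sd = 0.25,
                       n_expr_reps = 3L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_cgi = as.integer(n_cgi),
              cgi_length_range = as.integer(cgi_length_range),
              background_gc = background_gc, cpg_depletion = cpg_depletion,
              n_rrbs_targets = as.integer(n_rrbs_targets),
              n_animals = as.integer(n_animals), groups = as.character(groups),
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              conversion_rate = conversion_rate,
              baseline_methylation = baseline_methylation,
              cgi_methylation = cgi_methylation,
              tss_dip_depth = tss_dip_depth,
              tss_dip_halfwidth = as.integer(tss_dip_halfwidth),
              n_dmr = as.integer(n_dmr), dmr_delta = dmr_delta,
              dmr_window = as.integer(dmr_window), animal_sd = animal_sd,
              n_controls = as.integer(n_controls),
              n_deg = as.integer(n_deg), deg_log2fc = deg_log2fc,
              expr_noise_sd = expr_noise_sd,
              n_expr_reps = as.integer(n_expr_reps))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c("background_gc", "cpg_depletion", "conversion_rate",
          "baseline_methylation", "cgi_methylation", "tss_dip_depth")
  for (f in fr) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("sim_config: '%s' must be a fraction in [0, 1]", f)
  }
  if (cfg$cpg_depletion <= 0)
    stopf("sim_config: 'cpg_depletion' must be in (0, 1]")
  if (cfg$n_animals < 2L)
    stopf("sim_config: need at least 2 animals for a paired test")
  if (length(cfg$groups) != 2L || anyDuplicated(cfg$groups))
    stopf("sim_config: 'groups' must be two distinct labels")
  if (length(cfg$cgi_length_range) != 2L ||
      cfg$cgi_length_range[1] > cfg$cgi_length_range[2] ||
      cfg$cgi_length_range[1] <= 200L)
    stopf("sim_config: 'cgi_length_range' must be an increasing pair > 200 bp")
  if (cfg$chrom_length < 10L * cfg$cgi_length_range[2])
    stopf("sim_config: 'chrom_length' must be at least 10x the maximum CGI length")
  if (cfg$mean_depth <= 0) stopf("sim_config: 'mean_depth' must be positive")
  if (cfg$depth_dispersion < 0 || cfg$animal_sd < 0 || cfg$expr_noise_sd < 0)
    stopf("sim_config: dispersions/sds must be non-negative")
  if (cfg$n_expr_reps < 2L)
    stopf("sim_config: need at least 2 expression replicates per group")
  if (cfg$dmr_delta < 0 || cfg$dmr_delta > 1)
    stopf("sim_config: 'dmr_delta' is a methylation-fraction difference in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("RRBS simulation configuration\n")
  cat(sprintf("  genome : %d x %s bp, GC %.2f, CpG retention %.2f\n",
              x$n_chrom, format(x$chrom_length, big.mark = ","),
              x$background_gc, x$cpg_depletion))
  cat(sprintf("  content: %d genes, %d CGIs, %d MspI target fragments\n",
              x$n_genes, x$n_cgi, x$n_rrbs_targets))
  cat(sprintf("  design : %d animals x {%s}, depth %.0fx, conversion %.3f\n",
              x$n_animals, paste(x$groups, collapse = ", "),
              x$mean_depth, x$conversion_rate))
  cat(sprintf("  truth  : %d DMR windows (delta %.2f), %d DEGs (|log2FC| %.1f)\n",
              x$n_dmr, x$dmr_delta, x$n_deg, x$deg_log2fc))
  invisible(x)
}
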