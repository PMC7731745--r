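#' Simulate paired true methylomes with planted DMRs
#'
#' Lays a true methylation surface over the CpGs observable after in-silico
#' RRBS: a high genome-wide baseline, hypomethylated CpG islands, a
#' methylation dip around transcription start sites, a per-animal random
#' effect on the logit scale shared between the two cell types of the same
#' animal (the paired structure), and `n_dmr` window-aligned group offsets of
#' +/- `dmr_delta` methylation fraction (positive = higher in the second
#' group, myogenic by default).
#'
#' @param genome output of [generate_genome()].
#' @param gene_models output of [generate_gene_models()] (or compatible).
#' @param cfg a [sim_config()] object.
#' @param regions data.frame chrom/start/end of observable intervals;
#'   defaults to the size-selected MspI fragments of `genome`.
#' @return an object of class `meth_surface`: list with `sites`
#'   (chrom, 0-based CpG position), `samples` (sample/animal/group), `m`
#'   (true methylation matrix, sites x samples), `control_sites` (non-CpG
#'   cytosines for conversion estimation) and `truth` (planted DMR windows
#'   with signed delta, per-animal effects).
#' @export
simulate_methylomes <- function(genome, gene_models, cfg, regions = NULL) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "methylome"))
  if (is.null(regions)) regions <- rrbs_fragments(genome$genome)
  if (nrow(regions) == 0L) stopf("simulate_methylomes: no observable regions")

  sites <- .sites_in_regions(genome$genome, regions, pattern = "CG")
  if (nrow(sites) == 0L) stopf("simulate_methylomes: no CpGs in regions")

  # baseline surface
  base <- rep(cfg$baseline_methylation, nrow(sites))
  base <- pmin(base, .mask_level(sites, genome$cgis, cfg$cgi_methylation))
  tss <- .tss_table(gene_models)
  near_tss <- .near_point(sites, tss, cfg$tss_dip_halfwidth)
  base[near_tss] <- pmin(base[near_tss],
                         cfg$baseline_methylation * (1 - cfg$tss_dip_depth))

  # plant DMRs on whole windows of the analysis grid
  w <- cfg$dmr_window
  win_key <- paste(sites$chrom, sites$pos %/% w)
  n_in_win <- table(win_key)
  eligible <- names(n_in_win)[n_in_win >= 4L]
  # exclude windows whose base level is not the flat baseline
  flat <- tapply(base == cfg$baseline_methylation, win_key, all)
  eligible <- eligible[flat[eligible]]
  if (cfg$n_dmr > length(eligible))
    stopf("simulate_methylomes: only %d eligible windows for %d DMRs",
          length(eligible), cfg$n_dmr)
  dmr_keys <- sample(eligible, cfg$n_dmr)
  signs <- sample(rep(c(1, -1), length.out = cfg$n_dmr))

  dmr_truth <- if (cfg$n_dmr > 0L) {
    parts <- strsplit(dmr_keys, " ")
    data.frame(chrom = vapply(parts, `[`, "", 1L),
               start = as.integer(vapply(parts, `[`, "", 2L)) * w,
               end = (as.integer(vapply(parts, `[`, "", 2L)) + 1L) * w,
               delta = signs * cfg$dmr_delta)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               delta = numeric(0))
  }
  site_delta <- numeric(nrow(sites))
  if (cfg$n_dmr > 0L)
    site_delta <- dmr_truth$delta[match(win_key, dmr_keys)]
  site_delta[is.na(site_delta)] <- 0

  animals <- paste0("animal", seq_len(cfg$n_animals))
  a_eff <- stats::rnorm(cfg$n_animals, 0, cfg$animal_sd)
  samples <- data.frame(
    sample = paste(rep(cfg$groups, each = cfg$n_animals),
                   rep(seq_len(cfg$n_animals), 2L), sep = "_"),
    animal = rep(animals, 2L),
    group = rep(cfg$groups, each = cfg$n_animals))

  m <- matrix(NA_real_, nrow(sites), nrow(samples),
              dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    ai <- match(samples$animal[j], animals)
    m_a <- inv_logit(logit(clamp01(base)) + a_eff[ai])
    off <- if (samples$group[j] == cfg$groups[2]) site_delta / 2 else -site_delta / 2
    m[, j] <- clamp01(m_a + off)
  }

  controls <- .sites_in_regions(genome$genome, regions, pattern = "C_no_G")
  if (nrow(controls) > cfg$n_controls)
    controls <- controls[sort(sample.int(nrow(controls), cfg$n_controls)), ,
                         drop = FALSE]
  rownames(controls) <- NULL

  structure(list(sites = sites, samples = samples, m = m,
                 control_sites = controls,
                 truth = list(dmrs = dmr_truth, animal_effects = a_eff)),
            class = "meth_surface")
}

# positions (0-based) of CpG cytosines, or of non-CpG cytosines, inside
# 0-based half-open regions
.sites_in_regions <- function(genome, regions, pattern = c("CG", "C_no_G")) {
  pattern <- match.arg(pattern)
  out <- lapply(unique(regions$chrom), function(ch) {
    s <- as.character(genome[[ch]])
    if (pattern == "CG") {
      hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
      pos <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
    } else {
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      isC <- chars == "C"
      nextG <- c(chars[-1] == "G", FALSE)
      pos <- which(isC & !nextG) - 1L
    }
    r <- regions[regions$chrom == ch, , drop = FALSE]
    keep <- IRanges::overlapsAny(
      IRanges::IRanges(pos + 1L, pos + 1L),
      IRanges::IRanges(r$start + 1L, r$end))
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, pos = pos[keep])
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame(chrom = character(0), pos = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# level for sites inside mask intervals, +Inf elsewhere (for pmin)
.mask_level <- function(sites, intervals, level) {
  out <- rep(Inf, nrow(sites))
  if (nrow(intervals) == 0L) return(out)
  for (ch in unique(intervals$chrom)) {
    i <- sites$chrom == ch
    if (!any(i)) next
    r <- intervals[intervals$chrom == ch, , drop = FALSE]
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(sites$pos[i] + 1L, sites$pos[i] + 1L),
      IRanges::IRanges(r$start + 1L, r$end))
    out[i][hit] <- level
  }
  out
}

.tss_table <- function(gm) {
  g <- gm$genes
  data.frame(chrom = g$chrom,
             pos = ifelse(g$strand == "+", g$start, g$end - 1L))
}

.near_point <- function(sites, points, halfwidth) {
  out <- logical(nrow(sites))
  for (ch in unique(points$chrom)) {
    i <- sites$chrom == ch
    if (!any(i)) next
    p <- points$pos[points$chrom == ch]
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(sites$pos[i] + 1L, sites$pos[i] + 1L),
      IRanges::IRanges(p - halfwidth + 1L, p + halfwidth))
    out[i][hit] <- TRUE
  }
  out
}

#' Simulate RRBS read counts from a true methylation surface
#'
#' Per CpG and sample, total depth is drawn from a negative binomial with
#' mean `mean_depth` (Poisson when `depth_dispersion = 0`) and the
#' methylated count from a binomial with success probability
#' `m + (1 - m) * (1 - conversion_rate)` — incomplete bisulfite conversion
#' leaves a fraction of unmethylated cytosines reading as methylated.
#' Non-CpG control cytosines (true methylation 0) are emitted alongside for
#' conversion-rate estimation.
#'
#' @param surface a `meth_surface` from [simulate_methylomes()].
#' @param cfg a [sim_config()] object.
#' @return a [cpg_counts] object; its `"controls"` attribute holds the
#'   non-CpG control counts (list with `sites`, `meth`, `total`).
#' @export
simulate_counts <- function(surface, cfg) {
  validate_sim_config(cfg)
  if (cfg$mean_depth <= 0) stopf("simulate_counts: 'mean_depth' must be positive")
  set.seed(stage_seed(cfg$seed, "counts"))
  n <- nrow(surface$sites); k <- nrow(surface$samples)

  draw_tot <- function(nn) {
    if (cfg$depth_dispersion > 0)
      stats::rnbinom(nn, mu = cfg$mean_depth, size = 1 / cfg$depth_dispersion)
    else
      stats::rpois(nn, cfg$mean_depth)
  }
  total <- matrix(draw_tot(n * k), n, k)
  p <- surface$m + (1 - surface$m) * (1 - cfg$conversion_rate)
  meth <- matrix(stats::rbinom(n * k, as.vector(total), as.vector(p)), n, k)
  dimnames(total) <- dimnames(meth) <- list(NULL, surface$samples$sample)

  nc <- nrow(surface$control_sites)
  ctot <- matrix(draw_tot(nc * k), nc, k)
  cmeth <- matrix(stats::rbinom(nc * k, as.vector(ctot),
                                1 - cfg$conversion_rate), nc, k)
  dimnames(ctot) <- dimnames(cmeth) <- list(NULL, surface$samples$sample)

  out <- cpg_counts(surface$sites, surface$samples, meth, total)
  attr(out, "controls") <- list(sites = surface$control_sites,
                                meth = cmeth, total = ctot)
  out
}

#' Simulate a replicated expression table with planted DEGs
#'
#' Log-normal per-replicate abundances; `n_deg` genes receive a group offset
#' of +/- `deg_log2fc` on the log2 scale in the second group (myogenic by
#' default).
#'
#' @param gene_models output of [generate_gene_models()].
#' @param cfg a [sim_config()] object.
#' @return list with `expr` (data.frame: gene_id plus `<group>_rep<k>`
#'   columns, linear scale) and `degs` (planted truth: gene_id, signed
#'   log2 fold change).
#' @export
simulate_expression <- function(gene_models, cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "expression"))
  gid <- gene_models$genes$gene_id
  ng <- length(gid)
  if (cfg$n_deg > ng) stopf("simulate_expression: n_deg exceeds gene count")
  base <- stats::rnorm(ng, mean = 6, sd = 1.5)
  deg_idx <- sample.int(ng, cfg$n_deg)
  sgn <- sample(rep(c(1, -1), length.out = cfg$n_deg))
  offset <- numeric(ng)
  offset[deg_idx] <- sgn * cfg$deg_log2fc

  cols <- list(gene_id = gid)
  for (g in cfg$groups) {
    for (r in seq_len(cfg$n_expr_reps)) {
      mu <- base + if (g == cfg$groups[2]) offset else 0
      cols[[paste0(g, "_rep", r)]] <-
        2^(mu + stats::rnorm(ng, 0, cfg$expr_noise_sd))
    }
  }
  expr <- as.data.frame(cols)
  attr(expr, "groups") <- cfg$groups
  degs <- data.frame(gene_id = gid[deg_idx], log2fc = sgn * cfg$deg_log2fc)
  degs <- degs[order(degs$gene_id), , drop = FALSE]
  rownames(degs) <- NULL
  list(expr = expr, degs = degs)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome, gene models, in-silico RRBS (MspI digest +
#' 225-290 bp size selection), true methylomes, read counts, and expression,
#' all driven by one seed with independent per-stage substreams.
#'
#' @param cfg a [sim_config()] object.
#' @return an object of class `rrbs_sim`: list with `cfg`, `genome`
#'   ([Biostrings::DNAStringSet]), `gene_models`, `fragments` (kept RRBS
#'   fragments), `surface`, `counts` (a [cpg_counts] with control counts in
#'   its `"controls"` attribute), `expression`, and `truth` (planted CGIs,
#'   DMR windows, DEGs).
#' @examples
#' sim <- simulate_rrbs(sim_config(seed = 7, n_chrom = 1, chrom_length = 2e5,
#'                                 n_rrbs_targets = 30, n_cgi = 3,
#'                                 n_genes = 8, n_dmr = 5))
#' sim$truth$dmrs
#' @export
simulate_rrbs <- function(cfg) {
  g <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, g)
  frags <- rrbs_fragments(g$genome)
  surf <- simulate_methylomes(g, gm, cfg, frags)
  counts <- simulate_counts(surf, cfg)
  ex <- simulate_expression(gm, cfg)
  structure(list(cfg = cfg, genome = g$genome, gene_models = gm,
                 fragments = frags, surface = surf, counts = counts,
                 expression = ex$expr,
                 truth = list(cgis = g$cgis, dmrs = surf$truth$dmrs,
                              degs = ex$degs,
                              animal_effects = surf$truth$animal_effects)),
            class = "rrbs_sim")
}

#' @export
print.rrbs_sim <- function(x, ...) {
  cat("Synthetic RRBS study\n")
  cat(sprintf("  %d chromosome(s); %d kept fragments; %d observable CpG dyads\n",
              length(x$genome), nrow(x$fragments), nrow(x$counts$sites)))
  cat(sprintf("  truth: %d CGIs, %d DMR windows, %d DEGs\n",
              nrow(x$truth$cgis), nrow(x$truth$dmrs), nrow(x$truth$degs)))
  invisible(x)
}
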